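params <- preprocessParams()

test_that("pruning flags channels by mean raw intensity at either wavelength", {
    I <- matrix(1, 46L, 300L)
    lo <- I; lo[5L, ] <- 5e-4          # below 0.001
    hi <- I; hi[9L, ] <- 20            # above 10
    rec <- makeRecording(lo, hi)
    rec <- pruneChannels(rec, params)
    expect_false(usableChannels(rec)[5L])
    expect_false(usableChannels(rec)[9L])
    expect_identical(sum(usableChannels(rec)), 44L)
    # boundary values are inclusive
    b <- matrix(1, 46L, 10L); b[1L, ] <- 0.001; b[2L, ] <- 10
    rec2 <- pruneChannels(makeRecording(b, b), params)
    expect_true(all(usableChannels(rec2)))
})

test_that("optical density obeys its defining identities", {
    rec <- pruneChannels(flatRecording(level = 2), params)
    od <- intensityToOD(rec)
    expect_true(all(od$od780 == 0) && all(od$od850 == 0))

    I <- matrix(1, 46L, 200L)
    I[3L, 7L] <- mean(c(rep(1, 199), NA)) # placeholder; recompute below
    I[3L, ] <- 1; I[3L, 7L] <- 0.1 + 0.9 / 200 # so channel mean is ~1
    Ibar <- rowMeans(I)
    rec <- pruneChannels(makeRecording(I, I), params)
    od <- intensityToOD(rec)
    expect_equal(unname(od$od780[3L, 7L]), -log10(I[3L, 7L] / Ibar[3L]),
                 tolerance = 1e-12)
    # exp-mean property: mean(10^-OD) == 1 exactly, per channel
    set.seed(8)
    Ir <- matrix(exp(rnorm(46 * 200, sd = 0.1)), 46L)
    rec <- pruneChannels(makeRecording(Ir, Ir), params)
    od <- intensityToOD(rec)
    expect_equal(unname(rowMeans(10^(-od$od780))), rep(1, 46),
                 tolerance = 1e-12)
    # non-positive sample on a usable channel is an error naming it
    Ib <- Ir; Ib[12L, 5L] <- 0
    expect_error(intensityToOD(pruneChannels(makeRecording(Ib, Ir), params)),
                 "12")
})

test_that("motion correction is a near no-op on clean signals and removes spikes", {
    fs <- 10
    t <- seq(0, 259.9, by = 1 / fs)
    smooth <- 0.05 * sin(2 * pi * 0.1 * t)
    od <- list(od780 = matrix(rep(smooth, each = 46L), 46L, byrow = FALSE),
               od850 = matrix(rep(smooth, each = 46L), 46L, byrow = FALSE))
    od$od780 <- matrix(smooth, 46L, length(t), byrow = TRUE)
    od$od850 <- od$od780
    cm <- correctMotion(od, fs, params)
    expect_identical(nrow(cm$segments), 0L)
    relrms <- sqrt(mean((cm$od$od780 - od$od780)^2)) / sqrt(mean(od$od780^2))
    expect_lt(relrms, 0.01)

    # all-zero series: unchanged, no segments
    z <- list(od780 = matrix(0, 46L, 500L), od850 = matrix(0, 46L, 500L))
    cmz <- correctMotion(z, fs, params)
    expect_identical(cmz$od$od780, z$od780)
    expect_identical(nrow(cmz$segments), 0L)

    # injected large spike: amplitude reduced >= 80%, segment reported
    set.seed(9)
    noise <- matrix(rnorm(46 * length(t), sd = 0.01), 46L)
    spiked <- noise
    spike <- 1.0 * exp(-0.5 * ((t - 130) / 0.15)^2)
    spiked[7L, ] <- spiked[7L, ] + spike
    ods <- list(od780 = spiked, od850 = noise)
    cms <- correctMotion(ods, fs, params)
    seg <- cms$segments[cms$segments$channel == 7L, ]
    expect_gt(nrow(seg), 0L)
    expect_true(any(seg$start_s < 130 & seg$end_s > 130))
    peakBefore <- max(abs(spiked[7L, ] - noise[7L, ]))
    peakAfter <- max(abs(cms$od$od780[7L, ] - noise[7L, ]))
    expect_lt(peakAfter, 0.2 * peakBefore)
})

test_that("compiled detection and wavelet kernels match their R references", {
    set.seed(10)
    X <- matrix(rnorm(1600 * 4, sd = 0.02), 1600L)
    X[300:305, 2L] <- X[300:305, 2L] + 1
    X[900, 3L] <- 3
    expect_identical(infnirs:::.motionFlags(X, 10, params) == TRUE,
                     infnirs:::.motionFlagsR(X, 10, params) == TRUE)
    expect_equal(infnirs:::.waveletCorrect(X, 0.8),
                 infnirs:::.waveletCorrectR(X, 0.8), tolerance = 1e-12)
    # periodic transform reconstructs exactly
    w <- infnirs:::.dwtForward(X)
    expect_equal(infnirs:::.dwtInverse(w$a, w$d), X, tolerance = 1e-12)
})

test_that("band-pass filter matches its frequency-response oracle", {
    fs <- 10
    t <- seq(0, 600, by = 1 / fs)
    gain <- function(f0) {
        y <- bandpassFilter(sin(2 * pi * f0 * t), fs)
        max(abs(y[1500:4500]))
    }
    expect_gt(gain(0.12), 0.9)   # mid-band passed
    expect_lt(gain(0.005), 0.1)  # drift removed
    expect_lt(gain(2.0), 0.1)    # cardiac proxy removed
    expect_identical(max(abs(bandpassFilter(rep(0, 1000), fs))), 0)
    expect_error(bandpassFilter(rnorm(100), fs = 0.9, band = c(0.03, 0.5)),
                 "Nyquist")
})

test_that("Beer-Lambert conversion is linear and needs both wavelengths", {
    mont <- defaultMontage()
    z <- list(od780 = matrix(0, 46L, 10L), od850 = matrix(0, 46L, 10L))
    conc <- odToConcentration(z, mont, params)
    expect_true(all(conc$HbO == 0) && all(conc$HbR == 0))
    set.seed(11)
    od <- list(od780 = matrix(rnorm(46 * 10), 46L),
               od850 = matrix(rnorm(46 * 10), 46L))
    c1 <- odToConcentration(od, mont, params)
    c3 <- odToConcentration(list(od780 = 3 * od$od780, od850 = 3 * od$od850),
                            mont, params)
    expect_equal(c3$HbO, 3 * c1$HbO, tolerance = 1e-12)
    expect_equal(c3$HbR, 3 * c1$HbR, tolerance = 1e-12)
    expect_error(odToConcentration(list(od780 = od$od780), mont, params),
                 "wavelength")
})

test_that("epoching applies the guard, looking, channel and participant rules", {
    fs <- 10
    nT <- 1200L
    conc <- list(HbO = matrix(0, 46L, nT), HbR = matrix(0, 46L, nT))
    ev <- data.frame(
        condition = rep(c("baseline", "bimodal", "baseline", "alternating"), 3L),
        onset_s = c(0, 10, 18, 28, 36, 46, 54, 64, 72, 82, 90, 100),
        duration_s = rep(c(10, 8, 8, 8), 3L))
    look <- rep(1, 6L)

    # artifact ending 3 s before an onset is inside the 5-s guard
    segs <- data.frame(channel = 2L, wavelength = "780",
                       start_s = 6.5, end_s = 7.0)
    ep <- epochAndReject(conc, ev, segs, look, fs, params)
    expect_true(ep@trials$motion_rejected[1L])
    expect_false(any(ep@trials$motion_rejected[-1L]))
    # ... but an artifact clear of every window rejects nothing
    segs2 <- data.frame(channel = 2L, wavelength = "780",
                        start_s = 120.5, end_s = 121.0)
    ep2 <- epochAndReject(conc, ev, segs2, look, fs, params)
    expect_false(any(ep2@trials$motion_rejected))

    # looking below 0.40 rejects the trial; the 0.40 tie is kept
    ep3 <- epochAndReject(conc, ev, segs2, c(0.35, 0.40, 1, 1, 1, 1), fs, params)
    expect_true(ep3@trials$looking_rejected[1L])
    expect_false(ep3@trials$looking_rejected[2L])

    # a channel hit on more than 3 trials is excluded; trials then survive
    segs4 <- data.frame(channel = 9L, wavelength = "780",
                        start_s = c(11, 29, 47, 65), end_s = c(12, 30, 48, 66))
    ep4 <- epochAndReject(conc, ev, segs4, look, fs, params)
    expect_false(ep4@channelUsable[9L])
    expect_false(any(ep4@trials$motion_rejected))
    expect_true(ep4@included)

    # fewer than 3 surviving trials in one condition excludes the participant
    # (stimulation order is bimodal, alternating, bimodal, ...)
    ep5 <- epochAndReject(conc, ev, segs2, c(0.1, 1, 1, 1, 1, 1), fs, params)
    expect_identical(sum(ep5@trials$surviving &
                         ep5@trials$condition == "bimodal"), 2L)
    expect_false(ep5@included)
    expect_identical(ep5@exclusionReason, "trials")

    # exactly 31 usable channels still passes the channel rule
    ep6 <- epochAndReject(conc, ev, segs2, look, fs, params,
                          usable = c(rep(TRUE, 31L), rep(FALSE, 15L)))
    expect_true(ep6@included)
    ep7 <- epochAndReject(conc, ev, segs2, look, fs, params,
                          usable = c(rep(TRUE, 30L), rep(FALSE, 16L)))
    expect_false(ep7@included)
    expect_identical(ep7@exclusionReason, "channels")

    # epochs running past the recording end are dropped with a warning
    short <- list(HbO = matrix(0, 46L, 1150L), HbR = matrix(0, 46L, 1150L))
    expect_warning(ep8 <- epochAndReject(short, ev, segs2, look, fs, params),
                   "past")
    expect_true(ep8@trials$past_end[6L])
})

test_that("window means match the quadrature oracle on an analytic response", {
    fs <- 10
    nT <- 700L
    tgrid <- (seq_len(nT) - 1L) / fs
    onset <- 20
    resp <- blockResponse(tgrid, onset, amplitude = 2, peak = 9, shape = 6)
    conc <- list(HbO = matrix(resp, 46L, nT, byrow = TRUE),
                 HbR = matrix(-0.3 * resp, 46L, nT, byrow = TRUE))
    ev <- data.frame(condition = c("baseline", "bimodal", "baseline",
                                   "alternating"),
                     onset_s = c(0, onset, onset + 8, 45),
                     duration_s = c(onset, 8, 17, 8))
    ep <- epochAndReject(conc, ev, data.frame(channel = integer(),
        wavelength = character(), start_s = numeric(), end_s = numeric()),
        c(1, 1), fs, params)
    wmt <- windowMeans(ep, params)

    # oracle: evaluate the convolution integral by quadrature at each sample
    # time, then average over the window samples
    g <- infnirs:::.blockGamma(9, 6, 8)
    dens <- function(u) stats::dgamma(u, shape = 6, rate = g$rate)
    oracleAt <- function(tt) {
        vapply(tt, function(u) {
            if (u <= 0) return(0)
            stats::integrate(dens, max(0, u - 8), u, rel.tol = 1e-10)$value
        }, 0)
    }
    peakVal <- stats::optimize(oracleAt, c(0, 40), maximum = TRUE)$objective
    for (w in c("W1", "W2")) {
        win <- params$windows[[w]]
        ts <- tgrid[tgrid >= onset + win[1L] & tgrid < onset + win[2L]] - onset
        oracle <- 2 * mean(oracleAt(ts)) / peakVal
        got <- wmt$mean[wmt$condition == "bimodal" & wmt$window == w &
                        wmt$channel == 1L & wmt$chromophore == "HbO"]
        expect_equal(got, oracle, tolerance = 1e-6)
    }
    # constant 1 uM epochs -> all window means 1
    concc <- list(HbO = matrix(1, 46L, nT), HbR = matrix(1, 46L, nT))
    epc <- epochAndReject(concc, ev, data.frame(channel = integer(),
        wavelength = character(), start_s = numeric(), end_s = numeric()),
        c(1, 1), fs, params)
    wmc <- windowMeans(epc, params)
    expect_true(all(abs(wmc$mean - 1) < 1e-12))
    # a rejected trial contributes to no mean
    epr <- epochAndReject(concc, ev, data.frame(channel = 3L,
        wavelength = "780", start_s = 21, end_s = 22), c(1, 1), fs, params)
    wmr <- windowMeans(epr, params)
    expect_false(any(wmr$condition == "bimodal"))
})

test_that("filtering after motion correction differs from filtering before it", {
    cfg <- cleanConfig(seed = 21, n = 1L, sessionLength = 120,
        artifact = list(spikeRatePerMin = 3, spikeAmp = 1.0,
                        shiftRatePerMin = 1, shiftAmp = 0.6))
    rec <- pruneChannels(simulateCohort(cfg)$recordings[[1L]], params)
    od <- intensityToOD(rec)
    fs <- samplingRate(rec)
    # canonical order: correct, then filter
    cm <- correctMotion(od, fs, params)
    canonical <- bandpassFilter(t(cm$od$od780), fs, params$band)
    # swapped order: filter, then correct
    odf <- list(od780 = t(bandpassFilter(t(od$od780), fs, params$band)),
                od850 = t(bandpassFilter(t(od$od850), fs, params$band)))
    swapped <- t(correctMotion(odf, fs, params)$od$od780)
    expect_gt(max(abs(canonical - swapped)), 1e-3)
})

test_that("attrition bookkeeping reproduces the simulator's ground truth", {
    cfg <- simulationConfig(nYounger = 10L, nOlder = 0L, seed = 31,
        sessionLength = 240,
        artifact = list(spikeRatePerMin = 1.2, spikeAmp = 0.9,
                        shiftRatePerMin = 0.5, shiftAmp = 0.6),
        attrition = list(pChannelMissing = 0.25, lookingShape1 = 3,
                         lookingShape2 = 2))
    sim <- simulateCohort(cfg)
    pp <- preprocessCohort(sim$recordings)
    for (id in names(sim$recordings)) {
        exp <- sim$truth[[id]]$expected
        qc <- pp$qc[pp$qc$participant == id, ]
        expect_identical(qc$n_usable_channels, sum(exp$usable))
        expect_identical(qc$included, exp$included)
        expect_identical(qc$exclusion_reason, exp$reason)
        expect_identical(qc$n_trials_bimodal, unname(exp$trialCounts["bimodal"]))
        expect_identical(qc$n_trials_alternating,
                         unname(exp$trialCounts["alternating"]))
    }
})
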