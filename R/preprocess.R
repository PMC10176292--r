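#' Preprocessing parameters
#'
#' All thresholds of the preprocessing pipeline, defaulting to the published
#' rules: raw-intensity pruning bounds 0.001-10 (channel-mean intensity, raw
#' units), wavelet outlier factor 0.8 (interquartile ranges), 0.03-0.50 Hz
#' band-pass, differential pathway factor 5.1, 25-s epochs (-5 to +20 s),
#' analysis windows -5-0 s (baseline), 5-10 s (W1) and 10-15 s (W2), channel
#' exclusion beyond 3 artifact-affected trials, the 31-of-46-channel and
#' 3-trials-per-condition participant rules, the 60% looking-away trial rule
#' (kept iff looking >= 0.40) and the 5-s pre-trial artifact guard.
#'
#' Motion detection (sliding 1-s window, amplitude > 0.4 OD or standard
#' deviation beyond 15x the series' median rolling SD, 1-s mask padding) and
#' the Daubechies-2 wavelet family are conventional defaults, exposed here
#' because the published description fixes only the wavelet outlier factor.
#'
#' @param intensityLo,intensityHi channel-mean raw-intensity pruning bounds.
#' @param waveletIqr wavelet detail-coefficient outlier threshold, in IQRs.
#' @param motionWindow,motionAmpThresh,motionSdThresh,maskPad motion-detection
#'   window (s), amplitude threshold (OD), SD multiplier, and mask padding (s).
#' @param band band-pass corner frequencies in Hz (high-pass, low-pass).
#' @param dpf differential pathway factor.
#' @param epochWindow epoch extent around stimulus onset, seconds.
#' @param windows named list of analysis windows (half-open, seconds).
#' @param maxArtifactTrials channel excluded when artifacts affect more trials
#'   than this.
#' @param minChannels,minTrialsPerCondition participant inclusion floors
#'   (inclusive: exactly 31 usable channels or 3 surviving trials pass).
#' @param minLooking trial kept iff its looking proportion is >= this value.
#' @param guard pre-trial artifact guard in seconds.
#' @return a validated `infnirs_params` list.
#' @export
preprocessParams <- function(intensityLo = 0.001, intensityHi = 10,
                             waveletIqr = 0.8,
                             motionWindow = 1, motionAmpThresh = 0.4,
                             motionSdThresh = 15, maskPad = 1,
                             band = c(0.03, 0.50), dpf = 5.1,
                             epochWindow = c(-5, 20),
                             windows = list(baseline = c(-5, 0),
                                            W1 = c(5, 10), W2 = c(10, 15)),
                             maxArtifactTrials = 3L, minChannels = 31L,
                             minTrialsPerCondition = 3L, minLooking = 0.40,
                             guard = 5) {
    p <- list(intensityLo = intensityLo, intensityHi = intensityHi,
        waveletIqr = waveletIqr, motionWindow = motionWindow,
        motionAmpThresh = motionAmpThresh, motionSdThresh = motionSdThresh,
        maskPad = maskPad, band = band, dpf = dpf, epochWindow = epochWindow,
        windows = windows, maxArtifactTrials = maxArtifactTrials,
        minChannels = minChannels, minTrialsPerCondition = minTrialsPerCondition,
        minLooking = minLooking, guard = guard)
    stopifnot(intensityLo > 0, intensityLo < intensityHi,
        band[1L] > 0, band[1L] < band[2L], dpf > 0,
        epochWindow[1L] < epochWindow[2L])
    for (w in windows)
        if (w[1L] < epochWindow[1L] || w[2L] > epochWindow[2L])
            stop("analysis windows must lie within the epoch window")
    class(p) <- "infnirs_params"
    p
}

#' Prune channels on raw intensity
#'
#' A channel is unusable when its mean raw intensity at either wavelength
#' falls outside the `[intensityLo, intensityHi]` pruning bounds.
#'
#' @param rec a [NirsRecording-class].
#' @param params a [preprocessParams()].
#' @return the recording with its `usable` flags set (retrieve with
#'   [usableChannels()]).
#' @export
pruneChannels <- function(rec, params = preprocessParams()) {
    m780 <- rowMeans(intensity(rec, "780"))
    m850 <- rowMeans(intensity(rec, "850"))
    ok <- m780 >= params$intensityLo & m780 <= params$intensityHi &
          m850 >= params$intensityLo & m850 <= params$intensityHi
    usableChannels(rec) <- unname(ok)
    rec
}

#' Convert intensity to optical density
#'
#' `dOD(t) = -log10(I(t) / mean(I))`, per channel and wavelength, with the
#' channel's own temporal mean as the reference so that `mean(10^-dOD) = 1`.
#'
#' @param rec a pruned [NirsRecording-class].
#' @return list of matrices `od780`, `od850` (channel x time); rows of
#'   unusable channels are `NA`.
#' @export
intensityToOD <- function(rec) {
    usable <- usableChannels(rec)
    out <- lapply(c("780", "850"), function(wl) {
        I <- intensity(rec, wl)
        bad <- usable & apply(I <= 0, 1L, any)
        if (any(bad))
            stop(sprintf("non-positive intensity on usable channel(s) %s at %s nm",
                 paste(which(bad), collapse = ", "), wl))
        od <- -log10(I / rowMeans(I))
        od[!usable, ] <- NA_real_
        od
    })
    names(out) <- c("od780", "od850")
    out
}

## ---- Daubechies-2 discrete wavelet transform (periodic), on columns ----

.dwtForward <- function(X) .dwt_cpp(X)

.dwtInverse <- function(a, d) .idwt_cpp(a, d)

.waveletDepth <- function(n) {
    L <- 0L
    while (n %% 2L == 0L && n %/% 2L >= 4L && L < 8L) {
        n <- n %/% 2L
        L <- L + 1L
    }
    L
}

# Zero detail coefficients whose distance from the per-level median exceeds
# `iqrFactor` interquartile ranges, then reconstruct.
.waveletCorrect <- function(X, iqrFactor) {
    .wavelet_correct_cpp(X, iqrFactor)
}

# Pure-R reference implementation of the wavelet correction, kept as the
# cross-check for the compiled path.
.waveletCorrectR <- function(X, iqrFactor) {
    depth <- .waveletDepth(nrow(X))
    if (depth == 0L) return(X)
    details <- vector("list", depth)
    a <- X
    for (lev in seq_len(depth)) {
        w <- .dwtForward(a)
        a <- w$a
        details[[lev]] <- w$d
    }
    for (lev in seq_len(depth)) {
        d <- details[[lev]]
        qs <- apply(d, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75),
                    names = FALSE)
        med <- qs[2L, ]
        iqr <- qs[3L, ] - qs[1L, ]
        out <- abs(sweep(d, 2L, med)) > rep(iqrFactor * iqr, each = nrow(d))
        d[out] <- 0
        details[[lev]] <- d
    }
    for (lev in rev(seq_len(depth)))
        a <- .dwtInverse(a, details[[lev]])
    a
}

## ---- motion detection and spline correction ----

# Column-wise cumulative sums in one pass (cumsum over the stacked vector,
# then per-column offset correction).
.colCumsum <- function(M) {
    cs <- matrix(cumsum(M), nrow(M), ncol(M))
    if (ncol(M) > 1L)
        cs <- sweep(cs, 2L, c(0, cs[nrow(M), -ncol(M)]))
    cs
}

# "Is any of the m flags within reach of sample j set?", per column, via
# cumulative sums.  `lo`/`hi` give, for each output row, the (inclusive)
# input-row range to inspect.
.rangeAny <- function(flag, lo, hi) {
    cs <- rbind(0L, .colCumsum(flag * 1L))
    (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) > 0L
}

# Sample-level motion flags: a sample is flagged when any covering 1-s window
# exceeds the amplitude threshold or 15x the series' median rolling SD.
.motionFlags <- function(X, fs, params) {
    w <- max(2L, as.integer(round(params$motionWindow * fs)))
    pad <- as.integer(round(params$maskPad * fs))
    .motion_flags_cpp(X, w, params$motionAmpThresh, params$motionSdThresh, pad)
}

# Pure-R reference implementation of the motion detection, kept as the
# cross-check for the compiled path.
.motionFlagsR <- function(X, fs, params) {
    n <- nrow(X)
    w <- max(2L, as.integer(round(params$motionWindow * fs)))
    if (n < w) return(matrix(FALSE, n, ncol(X)))
    amp <- .rollamp_cpp(X, w)
    cs1 <- rbind(0, .colCumsum(X))
    cs2 <- rbind(0, .colCumsum(X^2))
    s1 <- cs1[(w + 1L):(n + 1L), , drop = FALSE] - cs1[seq_len(n - w + 1L), , drop = FALSE]
    s2 <- cs2[(w + 1L):(n + 1L), , drop = FALSE] - cs2[seq_len(n - w + 1L), , drop = FALSE]
    sds <- sqrt(pmax((s2 - s1^2 / w) / (w - 1L), 0))
    medsd <- apply(sds, 2L, stats::median)
    winFlag <- amp > params$motionAmpThresh |
        sds > rep(params$motionSdThresh * pmax(medsd, .Machine$double.eps),
                  each = nrow(sds))
    # window flags -> sample flags (a sample inherits any covering window),
    # then dilate by the mask padding
    nw <- n - w + 1L
    j <- seq_len(n)
    flag <- .rangeAny(winFlag, pmax(j - w + 1L, 1L), pmin(j, nw))
    pad <- as.integer(round(params$maskPad * fs))
    if (pad > 0L)
        flag <- .rangeAny(flag, pmax(j - pad, 1L), pmin(j + pad, n))
    flag
}

.flagsToSegments <- function(flag, fs) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep], end = ends[keep],
               start_s = (starts[keep] - 1L) / fs, end_s = ends[keep] / fs)
}

# Subtract a smoothing-spline fit inside a detected segment and re-level the
# series so it is continuous across the corrected stretch (this is what
# removes baseline steps).
.splineSegment <- function(x, i1, i2) {
    len <- i2 - i1 + 1L
    y <- x[i1:i2]
    fit <- if (len >= 10L) {
        tryCatch(stats::smooth.spline(seq_len(len), y)$y,
                 error = function(e) stats::fitted(stats::lm(y ~ seq_len(len))))
    } else if (len >= 2L) {
        stats::fitted(stats::lm(y ~ seq_len(len)))
    } else y
    new <- y - fit
    new <- new - new[1L] + if (i1 > 1L) x[i1 - 1L] else 0
    delta <- new[len] - y[len]
    x[i1:i2] <- new
    if (i2 < length(x)) x[(i2 + 1L):length(x)] <- x[(i2 + 1L):length(x)] + delta
    x
}

#' Motion-artifact correction (detect, wavelet, spline)
#'
#' Three stages per usable channel and wavelength.  Detection: a sliding 1-s
#' window marks stretches whose peak-to-peak amplitude or standard deviation
#' exceeds the thresholds; marks are padded by the mask padding.  Wavelet:
#' a periodic Daubechies-2 decomposition of the whole series; detail
#' coefficients farther than `waveletIqr` interquartile ranges from their
#' level median are zeroed and the series reconstructed.  Spline: within each
#' detected segment the residual trajectory is replaced by its
#' smoothing-spline detrended version and the segment boundaries re-levelled
#' for continuity, which removes baseline steps.  The detected segments are
#' returned for the downstream trial-rejection rules.
#'
#' @param od list of optical-density matrices from [intensityToOD()].
#' @param fs sampling rate in Hz.
#' @param params a [preprocessParams()].
#' @return list with corrected `od` and a `segments` data.frame
#'   (`channel`, `wavelength`, `start_s`, `end_s`).
#' @export
correctMotion <- function(od, fs, params = preprocessParams()) {
    segsAll <- list()
    out <- od
    for (wl in c("od780", "od850")) {
        M <- od[[wl]]
        usable <- which(rowSums(is.na(M)) == 0L)
        if (!length(usable)) next
        X <- t(M[usable, , drop = FALSE])
        if (nrow(X) < 8L) {
            message("series too short for wavelet decomposition; spline-only correction")
            Xw <- X
            flags <- .motionFlags(X, fs, params)
        } else {
            flags <- .motionFlags(X, fs, params)
            Xw <- .waveletCorrect(X, params$waveletIqr)
        }
        for (k in which(colSums(flags) > 0L)) {
            segs <- .flagsToSegments(flags[, k], fs)
            if (nrow(segs)) {
                for (s in seq_len(nrow(segs)))
                    Xw[, k] <- .splineSegment(Xw[, k], segs$start[s], segs$end[s])
                segsAll[[length(segsAll) + 1L]] <- data.frame(
                    channel = unname(usable[k]),
                    wavelength = sub("od", "", wl),
                    start_s = segs$start_s, end_s = segs$end_s)
            }
        }
        out[[wl]][usable, ] <- t(Xw)
    }
    segments <- if (length(segsAll)) do.call(rbind, segsAll) else
        data.frame(channel = integer(), wavelength = character(),
                   start_s = numeric(), end_s = numeric())
    list(od = out, segments = segments)
}

.bpCache <- new.env(parent = emptyenv())

#' Zero-phase band-pass filter
#'
#' Third-order Butterworth band-pass (0.03-0.50 Hz by default) applied
#' forward and backward for zero phase, with odd-symmetric reflection padding
#' to suppress edge transients.  Removes slow drift and cardiac/respiratory
#' oscillations while passing the hemodynamic band.
#'
#' @param X numeric matrix, series in columns (or a vector).
#' @param fs sampling rate in Hz; must exceed twice the upper corner.
#' @param band corner frequencies in Hz.
#' @return filtered matrix (or vector), same shape.
#' @export
bandpassFilter <- function(X, fs, band = c(0.03, 0.50)) {
    if (band[2L] >= fs / 2)
        stop("upper band edge must lie below the Nyquist frequency")
    vec <- is.null(dim(X))
    X <- as.matrix(X)
    n <- nrow(X)
    bf <- signal::butter(3, band / (fs / 2), type = "pass")
    pad <- min(n - 1L, as.integer(30 * fs))
    Xp <- rbind(2 * rep(X[1L, ], each = pad) - X[(pad + 1L):2L, , drop = FALSE],
                X,
                2 * rep(X[n, ], each = pad) - X[(n - 1L):(n - pad), , drop = FALSE])
    # zero-phase: multiply the spectrum by the squared magnitude response of
    # the Butterworth filter (the forward-backward cascade), sampled at the
    # FFT bin frequencies (memoised per signal length and band)
    N <- nrow(Xp)
    key <- sprintf("%d|%.8g|%.8g|%.8g", N, fs, band[1L], band[2L])
    H2 <- .bpCache[[key]]
    if (is.null(H2)) {
        ew <- exp(-2i * pi * (seq_len(N) - 1L) / N)
        num <- rep(bf$b[1L] + 0i, N)
        den <- rep(bf$a[1L] + 0i, N)
        ep <- rep(1 + 0i, N)
        for (t in seq_len(length(bf$b) - 1L)) {
            ep <- ep * ew
            num <- num + bf$b[t + 1L] * ep
            den <- den + bf$a[t + 1L] * ep
        }
        H2 <- Mod(num / den)^2
        .bpCache[[key]] <- H2
    }
    out <- Re(stats::mvfft(stats::mvfft(Xp) * H2, inverse = TRUE)) / N
    out <- out[(pad + 1L):(pad + n), , drop = FALSE]
    if (vec) drop(out) else out
}

#' Modified Beer-Lambert conversion to haemoglobin concentrations
#'
#' Solves, per channel and sample, the 2x2 system
#' `dOD_lambda = (eps_HbO,lambda dHbO + eps_HbR,lambda dHbR) * d * DPF`
#' with `d` the source-detector separation and the same differential pathway
#' factor at both wavelengths.
#'
#' @param od list of optical-density matrices (`od780`, `od850`).
#' @param montage a [NirsMontage-class].
#' @param params a [preprocessParams()] (provides the DPF).
#' @return list of matrices `HbO` and `HbR` (channel x time, uM).
#' @export
odToConcentration <- function(od, montage = defaultMontage(),
                              params = preprocessParams()) {
    if (is.null(od$od780) || is.null(od$od850))
        stop("both wavelengths (od780, od850) are required per channel")
    E <- extinctionCoefficients()
    invE <- solve(E)
    L <- channelTable(montage)$separation_cm * params$dpf
    hbo <- (invE["HbO", "780"] * od$od780 + invE["HbO", "850"] * od$od850) / L
    hbr <- (invE["HbR", "780"] * od$od780 + invE["HbR", "850"] * od$od850) / L
    list(HbO = hbo, HbR = hbr)
}

#' Epoch concentrations and apply the inclusion rules
#'
#' Cuts -5 to +20-s epochs around stimulation onsets and applies, in order:
#' the excessive-artifact channel rule (a channel is excluded when artifact
#' segments intersect the guard-extended windows of more than
#' `maxArtifactTrials` trials), per-channel and global motion trial rejection
#' (an artifact on any remaining usable channel within `[onset - 5 s,
#' onset + 20 s]` rejects the trial), the looking rule (rejected when looking
#' < 0.40), and the participant rules (at least 31 usable channels and at
#' least 3 surviving trials per condition).
#'
#' @param conc list of `HbO`/`HbR` matrices from [odToConcentration()].
#' @param events the event schedule.
#' @param segments artifact segments from [correctMotion()].
#' @param looking per-trial looking proportions.
#' @param fs sampling rate in Hz.
#' @param params a [preprocessParams()].
#' @param usable logical pruning flags.
#' @param participant,ageGroup annotation carried through.
#' @return a [NirsEpochs-class] with the participant verdict in `included()`.
#' @export
epochAndReject <- function(conc, events, segments, looking, fs,
                           params = preprocessParams(),
                           usable = rep(TRUE, 46L),
                           participant = "p01", ageGroup = "younger") {
    stim <- events[events$condition %in% .CONDITIONS, , drop = FALSE]
    ntrial <- nrow(stim)
    nT <- ncol(conc$HbO)

    hits <- matrix(FALSE, ntrial, 46L)
    if (nrow(segments)) {
        for (s in seq_len(nrow(segments))) {
            ch <- segments$channel[s]
            hit <- segments$start_s[s] < stim$onset_s + params$epochWindow[2L] &
                   segments$end_s[s] > stim$onset_s - params$guard
            hits[, ch] <- hits[, ch] | hit
        }
    }
    artifactExcluded <- colSums(hits) > params$maxArtifactTrials
    channelUsable <- usable & !artifactExcluded

    motionGlobal <- rowSums(hits[, channelUsable, drop = FALSE]) > 0
    lookingRejected <- looking < params$minLooking

    i0 <- round(stim$onset_s * fs) + 1L
    nEp <- as.integer((params$epochWindow[2L] - params$epochWindow[1L]) * fs)
    off <- as.integer(params$epochWindow[1L] * fs)
    time <- (seq_len(nEp) - 1L + off) / fs
    pastEnd <- (i0 + off + nEp - 1L) > nT | (i0 + off) < 1L
    if (any(pastEnd))
        warning(sprintf("%d trial(s) extend past the recording and were dropped",
                        sum(pastEnd)))

    values <- array(NA_real_, c(nEp, ntrial, 46L, 2L),
        dimnames = list(NULL, NULL, NULL, .CHROMOPHORES))
    for (j in which(!pastEnd)) {
        idx <- (i0[j] + off):(i0[j] + off + nEp - 1L)
        values[, j, , "HbO"] <- t(conc$HbO[, idx, drop = FALSE])
        values[, j, , "HbR"] <- t(conc$HbR[, idx, drop = FALSE])
    }

    surviving <- !motionGlobal & !lookingRejected & !pastEnd
    counts <- vapply(.CONDITIONS, function(cc)
        sum(surviving & stim$condition == cc), 0L)
    enoughChannels <- sum(channelUsable) >= params$minChannels
    enoughTrials <- all(counts >= params$minTrialsPerCondition)
    reason <- if (enoughChannels && enoughTrials) "none"
        else if (!enoughChannels && !enoughTrials) "channels+trials"
        else if (!enoughChannels) "channels" else "trials"

    trials <- data.frame(condition = stim$condition, onset_s = stim$onset_s,
        looking = looking, looking_rejected = lookingRejected,
        past_end = pastEnd, motion_rejected = motionGlobal,
        surviving = surviving)

    new("NirsEpochs", values = values, time = time, trials = trials,
        motionRejected = hits, channelUsable = channelUsable,
        participant = participant, ageGroup = ageGroup,
        included = enoughChannels && enoughTrials, exclusionReason = reason)
}

setMethod("show", "NirsEpochs", function(object) {
    tr <- object@trials
    cat("NirsEpochs", object@participant, sprintf("(%s)", object@ageGroup), "\n")
    cat(sprintf("  %d trials (%d surviving), %d usable channels\n",
        nrow(tr), sum(tr$surviving), sum(object@channelUsable)))
    cat(sprintf("  participant %s (%s)\n",
        if (object@included) "included" else "EXCLUDED", object@exclusionReason))
})

#' Window means over surviving epochs
#'
#' For every condition, usable channel, chromophore and analysis window, the
#' mean over surviving trials of the within-window temporal mean.  Keys with
#' no surviving trials are absent, never zero-filled.
#'
#' @param epochs a [NirsEpochs-class].
#' @param params a [preprocessParams()].
#' @param prepandemic logical tag carried into the table.
#' @return `data.frame` with columns `participant`, `age_group`,
#'   `prepandemic`, `condition`, `channel`, `chromophore`, `window`, `mean`,
#'   `n_trials`.
#' @export
windowMeans <- function(epochs, params = preprocessParams(), prepandemic = TRUE) {
    tr <- epochs@trials
    rows <- list()
    chans <- which(epochs@channelUsable)
    for (w in names(params$windows)) {
        win <- params$windows[[w]]
        tidx <- epochs@time >= win[1L] & epochs@time < win[2L]
        for (cc in .CONDITIONS) {
            jj <- which(tr$surviving & tr$condition == cc)
            if (!length(jj)) next
            for (chrom in .CHROMOPHORES) {
                # trial x channel means over the window samples
                sub <- epochs@values[tidx, jj, chans, chrom, drop = FALSE]
                tm <- apply(sub, c(2L, 3L), mean)
                keep <- !epochs@motionRejected[jj, chans, drop = FALSE]
                tm[!keep] <- NA_real_
                m <- colMeans(tm, na.rm = TRUE)
                n <- colSums(!is.na(tm))
                ok <- n > 0L
                if (!any(ok)) next
                rows[[length(rows) + 1L]] <- data.frame(
                    participant = epochs@participant,
                    age_group = epochs@ageGroup,
                    prepandemic = prepandemic,
                    condition = cc, channel = chans[ok], chromophore = chrom,
                    window = w, mean = unname(m[ok]), n_trials = unname(n[ok]))
            }
        }
    }
    if (!length(rows))
        return(data.frame(participant = character(), age_group = character(),
            prepandemic = logical(), condition = character(), channel = integer(),
            chromophore = character(), window = character(), mean = numeric(),
            n_trials = integer()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# QC peak-latency metric: latency of the grand-mean response extremum (HbO
# maximum / HbR minimum) within the post-stimulus period.
.peakLatency <- function(epochs) {
    tr <- epochs@trials
    jj <- which(tr$surviving)
    chans <- which(epochs@channelUsable)
    if (!length(jj) || !length(chans)) return(NA_real_)
    post <- epochs@time >= 0
    lat <- vapply(.CHROMOPHORES, function(chrom) {
        m <- apply(epochs@values[post, jj, chans, chrom, drop = FALSE], 1L, mean)
        tt <- epochs@time[post]
        if (chrom == "HbO") tt[which.max(m)] else tt[which.min(m)]
    }, 0)
    mean(lat)
}

#' Preprocess one recording end-to-end
#'
#' Runs the stages in their canonical order: intensity pruning, optical
#' density, motion detection and wavelet/spline correction, exclusion
#' bookkeeping, band-pass filtering, Beer-Lambert conversion, epoching and
#' window means.
#'
#' @param rec a [NirsRecording-class].
#' @param params a [preprocessParams()].
#' @return list with `epochs` ([NirsEpochs-class]), `windowMeans` (empty when
#'   the participant is excluded), `segments`, and a one-row `qc` data.frame.
#' @export
preprocessRecording <- function(rec, params = preprocessParams()) {
    rec <- pruneChannels(rec, params)
    usable <- usableChannels(rec)
    fs <- samplingRate(rec)
    od <- intensityToOD(rec)
    cm <- correctMotion(od, fs, params)
    odF <- lapply(cm$od, function(M) {
        ch <- which(rowSums(is.na(M)) == 0L)
        if (length(ch)) M[ch, ] <- t(bandpassFilter(t(M[ch, , drop = FALSE]),
                                                    fs, params$band))
        M
    })
    names(odF) <- names(cm$od)
    conc <- odToConcentration(odF, montage(rec), params)
    epochs <- epochAndReject(conc, events(rec), cm$segments, looking(rec), fs,
        params, usable, participantId(rec), ageGroup(rec))
    prepan <- isTRUE(metadata(rec)$prepandemic)
    wm <- if (epochs@included) windowMeans(epochs, params, prepan) else
        windowMeans(epochs, params, prepan)[0, ]
    qc <- data.frame(participant = participantId(rec), age_group = ageGroup(rec),
        prepandemic = prepan,
        n_usable_channels = sum(epochs@channelUsable),
        n_trials_bimodal = sum(epochs@trials$surviving &
                               epochs@trials$condition == "bimodal"),
        n_trials_alternating = sum(epochs@trials$surviving &
                                   epochs@trials$condition == "alternating"),
        n_looking_rejected = sum(epochs@trials$looking_rejected),
        n_motion_rejected = sum(epochs@trials$motion_rejected),
        included = epochs@included, exclusion_reason = epochs@exclusionReason,
        peak_latency_s = .peakLatency(epochs))
    list(epochs = epochs, windowMeans = wm, segments = cm$segments, qc = qc)
}

#' Preprocess a cohort
#'
#' @param recordings list of [NirsRecording-class] objects.
#' @param params a [preprocessParams()].
#' @param keepEpochs keep the per-participant [NirsEpochs-class] objects
#'   (memory-heavy; default `FALSE`).
#' @return list with `windowMeans` (included participants only), `qc` (all
#'   participants) and optionally `epochs`.
#' @export
preprocessCohort <- function(recordings, params = preprocessParams(),
                             keepEpochs = FALSE) {
    res <- lapply(recordings, preprocessRecording, params = params)
    wm <- do.call(rbind, lapply(res, `[[`, "windowMeans"))
    qc <- do.call(rbind, lapply(res, `[[`, "qc"))
    rownames(wm) <- rownames(qc) <- NULL
    out <- list(windowMeans = wm, qc = qc)
    if (keepEpochs) out$epochs <- lapply(res, `[[`, "epochs")
    out
}
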