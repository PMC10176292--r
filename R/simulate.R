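#' Tabulated extinction coefficients
#'
#' Molar extinction coefficients of oxy- and deoxy-haemoglobin at the two
#' source wavelengths (780 and 850 nm), from the standard compiled absorption
#' spectra, expressed per micromolar and centimetre.  The 2x2 matrix is well
#' conditioned, which is what makes the two-wavelength Beer-Lambert inversion
#' stable.
#'
#' @return numeric matrix, rows `"780"`/`"850"`, columns `"HbO"`/`"HbR"`,
#'   units 1/(uM cm).
#' @export
extinctionCoefficients <- function() {
    matrix(c(735.4, 1103.5,
             1058.0, 691.3) * 1e-6,
           nrow = 2, byrow = TRUE,
           dimnames = list(c("780", "850"), c("HbO", "HbR")))
}

#' Simulation configuration
#'
#' Parameters of the synthetic-cohort generator.  The defaults emulate the
#' study paradigm: a block design with 8-s stimulation trials of two
#' conditions and 9-12-s jittered baselines (3 trials per condition every two
#' minutes), haemodynamic responses peaking around 9 s after onset,
#' anticorrelated HbO/HbR, physiological noise (cardiac, respiratory and
#' Mayer-wave oscillations plus drift and white noise), motion artifacts,
#' missing channels and looking-away behaviour.
#'
#' @param nYounger,nOlder participants per age group (defaults 20 and 22, the
#'   final usable sample sizes of the study being emulated).
#' @param samplingRate Hz (default 10).
#' @param sessionLength seconds of scheduled stimulation; must cover at least
#'   one 120-s cycle (default 240, i.e. 6 trials per condition).  The emitted
#'   recording carries an extra 20-s baseline tail so the final trial's epoch
#'   fits.
#' @param hrfPeak,hrfShape HRF peak latency (s) and gamma shape.
#' @param effects list of effect specifications, each a list with `channels`
#'   (integer ids), `amplitude` (peak HbO response to the alternating unimodal
#'   condition, uM) and `additivity` (`"super"`, `"sub"`, `"linear"` or
#'   `"none"`).  Super-additive effects give the bimodal condition 1.5x the
#'   alternating amplitude, sub-additive 0.5x, linear 1x; `"none"` responds
#'   identically in both conditions.  HbR follows as `hbrRatio` times HbO.
#' @param hbrRatio negative scalar coupling HbR to HbO (default -0.3).
#' @param noise list: `cardiacHz`, `cardiacAmp`, `respHz`, `respAmp`,
#'   `mayerHz`, `mayerAmp` (sinusoid frequencies in Hz and amplitudes in uM,
#'   random phase per channel), `driftAmp` (uM, random-walk scale) and
#'   `whiteSd` (uM).
#' @param artifact list: `spikeRatePerMin`, `shiftRatePerMin` (events per
#'   minute), `spikeAmp`, `shiftAmp` (optical-density units).  Artifacts are
#'   placed with at least 3.5 s clearance from every epoch-rule boundary so
#'   that the ground-truth exclusion audit is exact.
#' @param attrition list: `pChannelMissing` (per-channel dropout probability;
#'   dropped channels record a constant 5e-4 intensity and fail pruning) and
#'   `lookingShape1`/`lookingShape2` (Beta parameters of the per-trial looking
#'   proportion).
#' @param prepandemicFraction named numeric, fraction of each group tagged as
#'   tested before the pandemic cutoff.
#' @param baselineIntensity raw intensity level I0 (arbitrary units).
#' @param seed mandatory integer seed.
#' @return a validated `infnirs_sim_config` list.
#' @export
simulationConfig <- function(nYounger = 20L, nOlder = 22L,
                             samplingRate = 10, sessionLength = 240,
                             hrfPeak = 9, hrfShape = 6,
                             effects = list(), hbrRatio = -0.3,
                             noise = list(), artifact = list(), attrition = list(),
                             prepandemicFraction = c(younger = 0.85, older = 0.68),
                             baselineIntensity = 1.0, seed) {
    if (missing(seed)) stop("a seed is mandatory for simulation configs")
    noise <- utils::modifyList(list(cardiacHz = 2.0, cardiacAmp = 0.1,
        respHz = 0.6, respAmp = 0.1, mayerHz = 0.1, mayerAmp = 0.1,
        driftAmp = 0.1, whiteSd = 0.2), noise)
    artifact <- utils::modifyList(list(spikeRatePerMin = 0, shiftRatePerMin = 0,
        spikeAmp = 0.8, shiftAmp = 0.5), artifact)
    attrition <- utils::modifyList(list(pChannelMissing = 0.02,
        lookingShape1 = 8, lookingShape2 = 2), attrition)
    cfg <- list(nYounger = nYounger, nOlder = nOlder, samplingRate = samplingRate,
        sessionLength = sessionLength, hrfPeak = hrfPeak, hrfShape = hrfShape,
        effects = effects, hbrRatio = hbrRatio, noise = noise, artifact = artifact,
        attrition = attrition, prepandemicFraction = prepandemicFraction,
        baselineIntensity = baselineIntensity, seed = as.integer(seed))
    stopifnot(nYounger >= 0, nOlder >= 0, samplingRate > 0,
        attrition$pChannelMissing >= 0, attrition$pChannelMissing <= 1,
        artifact$spikeRatePerMin >= 0, artifact$shiftRatePerMin >= 0,
        all(is.finite(unlist(noise))), hbrRatio <= 0)
    for (ef in effects) {
        if (!all(ef$channels %in% 1:46))
            stop("effect channel ids must lie in the 46-channel montage")
        if (!ef$additivity %in% c("super", "sub", "linear", "none"))
            stop("additivity must be super, sub, linear or none")
        if (!is.finite(ef$amplitude)) stop("effect amplitudes must be finite")
    }
    class(cfg) <- "infnirs_sim_config"
    cfg
}

.additivityFactor <- function(additivity) {
    switch(additivity, super = 1.5, sub = 0.5, linear = 1, none = 1)
}

#' Pseudo-random block-design event schedule
#'
#' Lays out the paradigm timing: within each 120-s cycle, 6 stimulation trials
#' of 8 s (exactly 3 per condition, in pseudo-random order with no condition
#' occurring three times in a row), each preceded by a baseline period whose
#' duration is drawn uniformly from 9-12 s.  Because 6 x 8 s plus at most
#' 6 x 12 s is exactly 120 s, every cycle fits its window; any remainder is
#' emitted as a trailing baseline event.
#'
#' @param sessionLength total scheduled length in seconds; at least 120.
#' @param seed optional integer; when given, the schedule is drawn from a
#'   private RNG stream and the caller's RNG state is untouched.
#' @return `data.frame` with columns `condition`, `onset_s`, `duration_s`.
#' @examples
#' sched <- makeSchedule(240, seed = 1)
#' table(sched$condition)
#' @export
makeSchedule <- function(sessionLength, seed = NULL) {
    if (sessionLength < 120)
        stop("session must cover at least one 120-s cycle")
    if (!is.null(seed)) {
        state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv()))
        set.seed(seed)
    }
    ncycle <- floor(sessionLength / 120)
    rows <- vector("list", 0L)
    tail2 <- character(0)
    for (k in seq_len(ncycle)) {
        repeat {
            labels <- sample(rep(.CONDITIONS, 3L))
            if (max(rle(c(tail2, labels))$lengths) < 3L) break
        }
        tail2 <- labels[5:6]
        jitter <- stats::runif(6L, 9, 12)
        t <- 120 * (k - 1)
        for (j in 1:6) {
            rows[[length(rows) + 1L]] <- data.frame(
                condition = "baseline", onset_s = t, duration_s = jitter[j])
            t <- t + jitter[j]
            rows[[length(rows) + 1L]] <- data.frame(
                condition = labels[j], onset_s = t, duration_s = 8)
            t <- t + 8
        }
        if (t < 120 * k)
            rows[[length(rows) + 1L]] <- data.frame(
                condition = "baseline", onset_s = t, duration_s = 120 * k - t)
    }
    ev <- do.call(rbind, rows)
    rownames(ev) <- NULL
    ev
}

#' Forward optical model (concentration to intensity)
#'
#' The exact algebraic inverse of the modified Beer-Lambert conversion: the
#' concentration changes are mapped to optical-density changes through the
#' extinction-coefficient matrix, the source-detector separation and the
#' differential pathway factor, and then to raw intensities as
#' `I = I0 * 10^(-dOD)`.
#'
#' @param hbo,hbr numeric matrices (channel x time) of concentration changes
#'   in uM.
#' @param montage a [NirsMontage-class] providing per-channel separations.
#' @param dpf differential pathway factor (default 5.1, both wavelengths).
#' @param I0 baseline intensity (scalar or per-channel vector).
#' @return list with intensity matrices `wl780` and `wl850`; the `"I0"`
#'   attribute records the reference level.
#' @export
forwardModel <- function(hbo, hbr, montage = defaultMontage(), dpf = 5.1, I0 = 1) {
    E <- extinctionCoefficients()
    if (abs(det(E)) < 1e-12) stop("extinction matrix is singular")
    L <- channelTable(montage)$separation_cm
    od780 <- (E["780", "HbO"] * hbo + E["780", "HbR"] * hbr) * L * dpf
    od850 <- (E["850", "HbO"] * hbo + E["850", "HbR"] * hbr) * L * dpf
    out <- list(wl780 = I0 * 10^(-od780), wl850 = I0 * 10^(-od850))
    attr(out, "I0") <- I0
    out
}

# Sinusoidal + drift + white physiological noise for one participant:
# channels x time, random phase per channel and component.
.physioNoise <- function(nchan, t, noise) {
    out <- matrix(stats::rnorm(nchan * length(t), sd = noise$whiteSd), nchan)
    for (comp in list(c(noise$cardiacHz, noise$cardiacAmp),
                      c(noise$respHz, noise$respAmp),
                      c(noise$mayerHz, noise$mayerAmp))) {
        phase <- stats::runif(nchan, 0, 2 * pi)
        out <- out + comp[2L] *
            (cos(phase) %o% cos(2 * pi * comp[1L] * t) -
             sin(phase) %o% sin(2 * pi * comp[1L] * t))
    }
    drift <- t(apply(matrix(stats::rnorm(nchan * length(t)), nchan), 1L, cumsum)) *
        noise$driftAmp / sqrt(length(t))
    out + drift
}

# Artifact onset times with clearance from every epoch-rule boundary, so that
# detection padding cannot move an artifact across a rule edge.
.artifactTimes <- function(n, sessionLength, boundaries, clearance = 3.5) {
    keep <- numeric(0)
    tries <- 0L
    while (length(keep) < n && tries < 500L * max(n, 1L)) {
        t0 <- stats::runif(1L, clearance, sessionLength - clearance)
        if (all(abs(t0 - boundaries) >= clearance)) keep <- c(keep, t0)
        tries <- tries + 1L
    }
    keep
}

# Expected exclusion bookkeeping from planted ground truth, mirroring the
# published rules: artifact channels (> maxArtifactTrials affected trials),
# trial rejection (artifact within [-5, +20) of onset, or looking below the
# 40% floor), 31-channel and 3-trial participant rules.
.expectedExclusions <- function(ev, segments, dropped, looking, params) {
    stim <- ev[ev$condition %in% .CONDITIONS, , drop = FALSE]
    nch <- 46L
    hits <- matrix(FALSE, nrow(stim), nch)
    if (nrow(segments)) {
        for (s in seq_len(nrow(segments))) {
            ch <- segments$channel[s]
            hit <- segments$start_s[s] < stim$onset_s + params$epochWindow[2L] &
                   segments$end_s[s] > stim$onset_s - params$guard
            hits[, ch] <- hits[, ch] | hit
        }
    }
    artifactExcluded <- colSums(hits) > params$maxArtifactTrials
    usable <- !(seq_len(nch) %in% dropped) & !artifactExcluded
    motionRejected <- rowSums(hits[, usable, drop = FALSE]) > 0
    lookingRejected <- looking < params$minLooking
    surviving <- !motionRejected & !lookingRejected
    counts <- vapply(.CONDITIONS, function(cc) sum(surviving & stim$condition == cc), 0L)
    enoughChannels <- sum(usable) >= params$minChannels
    enoughTrials <- all(counts >= params$minTrialsPerCondition)
    reason <- if (enoughChannels && enoughTrials) "none"
        else if (!enoughChannels && !enoughTrials) "channels+trials"
        else if (!enoughChannels) "channels" else "trials"
    list(usable = usable, artifactExcluded = artifactExcluded,
         motionRejected = motionRejected, lookingRejected = lookingRejected,
         trialCounts = counts, included = enoughChannels && enoughTrials,
         reason = reason)
}

#' Simulate an across-participant pattern set directly
#'
#' Generates participant x condition activation patterns at the window-means
#' level (bypassing the raw-signal stages), for calibrating the decoding
#' stack in isolation: per participant and channel, activations are unit
#' Gaussians, with `effect` added to the bimodal condition on
#' `effectChannels`; whole channels go missing per participant with
#' probability `pMissing`; the result is z-scored within channel as in
#' [buildPatterns()].
#'
#' @param nParticipants participants (two patterns each).
#' @param channels integer channel ids.
#' @param effect bimodal-minus-alternating shift, in noise-SD units.
#' @param effectChannels channels carrying the effect.
#' @param pMissing per-participant, per-channel missingness probability.
#' @param seed integer seed.
#' @return a [NirsPatternSet-class].
#' @export
simulatePatternSet <- function(nParticipants, channels = 1:46, effect = 0,
                               effectChannels = integer(), pMissing = 0,
                               seed) {
    set.seed(seed)
    n <- nParticipants
    k <- length(channels)
    M <- matrix(stats::rnorm(2L * n * k), 2L * n, k,
                dimnames = list(NULL, as.character(channels)))
    labels <- rep(c(1, -1), n)   # bimodal, alternating per participant
    if (length(effectChannels))
        M[labels > 0, match(effectChannels, channels)] <-
            M[labels > 0, match(effectChannels, channels)] + effect
    if (pMissing > 0) {
        for (i in seq_len(n)) {
            drop <- stats::runif(k) < pMissing
            if (sum(!drop) < 1L) drop[sample(k, 1L)] <- FALSE
            M[c(2L * i - 1L, 2L * i), drop] <- NA_real_
        }
    }
    M <- scale(M)
    attr(M, "scaled:center") <- attr(M, "scaled:scale") <- NULL
    new("NirsPatternSet", values = M, labels = labels,
        participants = rep(sprintf("p%03d", seq_len(n)), each = 2L),
        channels = as.integer(channels), subset = "all",
        chromophore = "HbO", window = "W2", ageGroup = "all")
}

#' Simulate a cohort of infant fNIRS recordings with known ground truth
#'
#' Per participant, concentration time courses are built as analytic
#' block-convolved gamma responses scaled by condition amplitudes (the
#' additivity type sets the bimodal amplitude relative to the alternating
#' amplitude), HbR is coupled to HbO by `hbrRatio` with independent noise, and
#' the result is pushed through the forward optical model to raw intensities.
#' Motion artifacts (optical-density spikes and baseline shifts) and channel
#' dropout are then applied, and per-trial looking proportions drawn.  The
#' returned ground truth records, for every participant, the planted effect
#' map, artifact segments, dropped channels, looking values, and the exclusion
#' bookkeeping the preprocessing rules are expected to reproduce.
#'
#' @param config a [simulationConfig()].
#' @return list with `recordings` (list of [NirsRecording-class]), `truth`
#'   (per-participant ground-truth list) and `config`.
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "infnirs_sim_config"))
    set.seed(config$seed)
    mont <- defaultMontage()
    fs <- config$samplingRate
    params <- preprocessParams(dpf = 5.1)
    nT <- as.integer((config$sessionLength + 20) * fs)
    t <- (seq_len(nT) - 1L) / fs

    # per-channel, per-condition peak HbO amplitudes from the effect list
    ampA <- ampB <- numeric(46L)
    for (ef in config$effects) {
        ampA[ef$channels] <- ef$amplitude
        ampB[ef$channels] <- ef$amplitude * .additivityFactor(ef$additivity)
    }

    groups <- c(rep("younger", config$nYounger), rep("older", config$nOlder))
    ids <- c(sprintf("y%02d", seq_len(config$nYounger)),
             sprintf("o%02d", seq_len(config$nOlder)))
    npre <- c(younger = round(config$prepandemicFraction[["younger"]] * config$nYounger),
              older = round(config$prepandemicFraction[["older"]] * config$nOlder))
    prepan <- c(seq_len(config$nYounger) <= npre[["younger"]],
                seq_len(config$nOlder) <= npre[["older"]])

    recordings <- vector("list", length(ids))
    truth <- vector("list", length(ids))
    names(recordings) <- names(truth) <- ids

    for (i in seq_along(ids)) {
        ev <- makeSchedule(config$sessionLength)
        stim <- ev[ev$condition %in% .CONDITIONS, , drop = FALSE]

        respB <- respA <- numeric(nT)
        for (j in seq_len(nrow(stim))) {
            r <- blockResponse(t, stim$onset_s[j], duration = 8, amplitude = 1,
                               peak = config$hrfPeak, shape = config$hrfShape)
            if (stim$condition[j] == "bimodal") respB <- respB + r else respA <- respA + r
        }
        hboSig <- ampB %o% respB + ampA %o% respA
        hbo <- hboSig + .physioNoise(46L, t, config$noise)
        hbrNoise <- .physioNoise(46L, t, config$noise) * abs(config$hbrRatio)
        hbr <- config$hbrRatio * hboSig + hbrNoise

        inten <- forwardModel(hbo, hbr, mont, dpf = params$dpf,
                              I0 = config$baselineIntensity)
        od780 <- -log10(inten$wl780 / config$baselineIntensity)
        od850 <- -log10(inten$wl850 / config$baselineIntensity)

        dropped <- which(stats::runif(46L) < config$attrition$pChannelMissing)
        alive <- setdiff(1:46, dropped)

        boundaries <- c(stim$onset_s - params$guard,
                        stim$onset_s + params$epochWindow[2L])
        segs <- list()
        art <- config$artifact
        for (type in c("spike", "shift")) {
            rate <- if (type == "spike") art$spikeRatePerMin else art$shiftRatePerMin
            nArt <- stats::rpois(1L, rate * config$sessionLength / 60)
            if (nArt == 0L || length(alive) == 0L) next
            t0s <- .artifactTimes(nArt, config$sessionLength, boundaries)
            for (t0 in t0s) {
                ch <- if (length(alive) == 1L) alive else sample(alive, 1L)
                sgn <- sample(c(-1, 1), 1L)
                shape <- if (type == "spike") {
                    art$spikeAmp * sgn * exp(-0.5 * ((t - t0) / 0.15)^2)
                } else {
                    art$shiftAmp * sgn * (t >= t0)
                }
                od780[ch, ] <- od780[ch, ] + shape
                od850[ch, ] <- od850[ch, ] + shape
                segs[[length(segs) + 1L]] <- data.frame(
                    channel = ch, start_s = t0 - 0.5, end_s = t0 + 0.5, type = type)
            }
        }
        segments <- if (length(segs)) do.call(rbind, segs) else
            data.frame(channel = integer(), start_s = numeric(),
                       end_s = numeric(), type = character())

        wl780 <- config$baselineIntensity * 10^(-od780)
        wl850 <- config$baselineIntensity * 10^(-od850)
        if (length(dropped)) {
            wl780[dropped, ] <- 5e-4
            wl850[dropped, ] <- 5e-4
        }

        look <- stats::rbeta(nrow(stim), config$attrition$lookingShape1,
                             config$attrition$lookingShape2)

        recordings[[i]] <- NirsRecording(wl780, wl850, montage = mont,
            samplingRate = fs, events = ev, looking = look,
            participantId = ids[i], ageGroup = groups[i], prepandemic = prepan[i])
        truth[[i]] <- list(
            effectHbO = cbind(bimodal = ampB, alternating = ampA),
            artifacts = segments, dropped = dropped, looking = look,
            expected = .expectedExclusions(ev, segments, dropped, look, params))
    }
    list(recordings = recordings, truth = truth, config = config)
}
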