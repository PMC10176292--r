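# Shared fixture builders.  Everything is generated in code; sizes are kept
# small so the default run stays fast.

# A recording with hand-chosen intensity matrices and a minimal valid
# schedule (one cycle), for exercising single preprocessing stages.
makeRecording <- function(wl780, wl850, fs = 10, events = NULL, looking = NULL,
                          participant = "t01", ageGroup = "younger") {
    if (is.null(events)) {
        nstim <- 2L
        events <- data.frame(
            condition = c("baseline", "bimodal", "baseline", "alternating"),
            onset_s = c(0, 10, 18, 28), duration_s = c(10, 8, 10, 8))
    }
    nstim <- sum(events$condition %in% c("bimodal", "alternating"))
    if (is.null(looking)) looking <- rep(1, nstim)
    NirsRecording(wl780, wl850, samplingRate = fs, events = events,
                  looking = looking, participantId = participant,
                  ageGroup = ageGroup)
}

# Constant-intensity recording: flat optical density, no artifacts.
flatRecording <- function(level = 1, nT = 700L, fs = 10, ...) {
    I <- matrix(level, 46L, nT)
    makeRecording(I, I, fs = fs, ...)
}

# Small clean cohort simulation config (no artifacts, no dropout).
cleanConfig <- function(seed, n = 6L, effects = list(), sessionLength = 240,
                        ...) {
    simulationConfig(nYounger = n, nOlder = 0L, seed = seed,
        sessionLength = sessionLength, effects = effects,
        attrition = list(pChannelMissing = 0), ...)
}

# A window-means table built directly from per-participant values:
# `values` is a named list condition -> matrix [participant x window-values]
# for one channel/chromophore, with windows baseline/W1/W2.
wmFixture <- function(bimodal, alternating, channel = 1L, chromophore = "HbO",
                      ageGroup = "younger", participants = NULL) {
    n <- nrow(bimodal)
    if (is.null(participants)) participants <- sprintf("p%02d", seq_len(n))
    rows <- list()
    for (i in seq_len(n)) {
        for (cc in c("bimodal", "alternating")) {
            v <- if (cc == "bimodal") bimodal[i, ] else alternating[i, ]
            rows[[length(rows) + 1L]] <- data.frame(
                participant = participants[i], age_group = ageGroup,
                prepandemic = TRUE, condition = cc, channel = channel,
                chromophore = chromophore,
                window = c("baseline", "W1", "W2"),
                mean = as.numeric(v), n_trials = 5L)
        }
    }
    do.call(rbind, rows)
}

# Brute-force Benjamini-Hochberg step-up, as an oracle independent of
# p.adjust: adjusted p_(i) = min over j >= i of p_(j) * m / j, capped at 1.
bhStepUpOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(m)
    run <- 1
    for (i in m:1) {
        run <- min(run, ps[i] * m / i)
        adj[i] <- run
    }
    out <- numeric(m)
    out[o] <- adj
    out
}
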