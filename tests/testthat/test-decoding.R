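# Window-means table with per-(participant, channel) values laid out for
# decoding tests: `mat` is participants x channels per condition.
wmFromPatterns <- function(bim, alt, window = "W2", chromophore = "HbO",
                           ageGroup = "younger") {
    n <- nrow(bim)
    rows <- list()
    for (i in seq_len(n)) {
        for (cc in c("bimodal", "alternating")) {
            v <- if (cc == "bimodal") bim[i, ] else alt[i, ]
            keep <- !is.na(v)
            if (!any(keep)) next
            rows[[length(rows) + 1L]] <- data.frame(
                participant = sprintf("p%02d", i), age_group = ageGroup,
                prepandemic = i <= ceiling(n / 2), condition = cc,
                channel = which(keep), chromophore = chromophore,
                window = window, mean = v[keep], n_trials = 5L)
        }
    }
    do.call(rbind, rows)
}

test_that("pattern construction z-scores channels and respects subsets", {
    set.seed(21)
    bim <- matrix(rnorm(10 * 46), 10L)
    alt <- matrix(rnorm(10 * 46), 10L)
    bim[3L, 12L] <- alt[3L, 12L] <- NA  # participant 3 misses channel 12
    wm <- wmFromPatterns(bim, alt)
    ps <- buildPatterns(wm, chromophore = "HbO", window = "W2", subset = "all")
    expect_s4_class(ps, "NirsPatternSet")
    expect_identical(dim(ps@values), c(20L, 46L))
    # per-channel mean 0 / sd 1 over non-missing entries
    expect_true(all(abs(colMeans(ps@values, na.rm = TRUE)) < 1e-12))
    expect_true(all(abs(apply(ps@values, 2L, sd, na.rm = TRUE) - 1) < 1e-12))
    # missing entries stay missing, never imputed
    expect_true(is.na(ps@values[5L, 12L]) && is.na(ps@values[6L, 12L]))
    expect_identical(sum(is.na(ps@values[, 12L])), 2L)
    # hemisphere subsets follow the montage
    left <- buildPatterns(wm, subset = "left")
    expect_identical(left@channels, 1:23)
    right <- buildPatterns(wm, subset = "right")
    expect_identical(right@channels, 24:46)
    # zero-variance channel dropped with a warning
    bim2 <- bim; alt2 <- alt
    bim2[, 7L] <- alt2[, 7L] <- 3
    expect_warning(ps2 <- buildPatterns(wmFromPatterns(bim2, alt2)), "7")
    expect_false(7L %in% ps2@channels)
})

test_that("LOPO classifies a separable construction perfectly and masks folds", {
    half <- c(rep(1, 23L), rep(-1, 23L))
    bim <- matrix(rep(half, each = 10L), 10L) + matrix(rnorm(460, sd = 0.05), 10L)
    alt <- -bim + matrix(rnorm(460, sd = 0.05), 10L)
    ps <- buildPatterns(wmFromPatterns(bim, alt))
    acc <- lopoAccuracy(ps)
    expect_identical(acc$accuracy, 1)
    expect_identical(acc$nFolds, 10L)
    expect_identical(acc$accuracyBothCorrect, 1)

    # fold masking: channels missing for the test participant are dropped
    # from that fold's training patterns (decision unchanged by their values)
    bimM <- bim; altM <- alt
    bimM[1L, 40:46] <- altM[1L, 40:46] <- NA
    psM <- buildPatterns(wmFromPatterns(bimM, altM))
    accM <- lopoAccuracy(psM)
    # corrupt the masked channels for every OTHER participant wildly: fold 1's
    # predictions must not change under the test-only mask rule
    bimC <- bimM; bimC[2:10, 40:46] <- 50
    psC <- buildPatterns(wmFromPatterns(bimC, altM))
    f1 <- lopoAccuracy(psM, maskRule = "test")$folds
    f2 <- lopoAccuracy(psC, maskRule = "test")$folds
    expect_identical(f1$predicted[f1$participant == "p01"],
                     f2$predicted[f2$participant == "p01"])
    expect_identical(accM$nFolds, 10L)

    # fewer than 3 participants is an error
    ps3 <- simulatePatternSet(2, seed = 1)
    expect_error(lopoAccuracy(ps3), "3 participants")
})

test_that("decoding engine agrees with the reference SVM implementation", {
    skip_if_not_installed("e1071")
    set.seed(22)
    for (r in 1:25) {
        n <- 2L * sample(4:12, 1L)
        p <- sample(5:46, 1L)
        X <- matrix(rnorm(n * p), n)
        if (r %% 2 == 0) X[seq(1, n, 2), seq_len(3)] <-
            X[seq(1, n, 2), seq_len(3)] + 1
        y <- rep(c(1, -1), n / 2)
        fit <- infnirs:::.svm_linear_cpp(X, y, 1)
        f <- drop(X %*% fit$w) + fit$b
        ref <- e1071::svm(X, factor(y), kernel = "linear", cost = 1,
                          scale = FALSE)
        pref <- as.numeric(as.character(predict(ref, X)))
        disagree <- (sign(f) != pref) & abs(f) > 1e-3
        expect_false(any(disagree))
    }
})

test_that("permutation p follows the inclusive estimator and its limits", {
    # strong planted signal: observed beats all permutations except the
    # label-preserving ones; with 1000 permutations the floor is 1/1001
    ps <- simulatePatternSet(12, effect = 6, effectChannels = 1:20, seed = 30)
    perm <- permutationP(ps, nPerm = 1000L, seed = 31)
    expect_identical(perm$nPerm, 1000L)
    expect_equal(perm$observed, 1)
    # identical-sign permutations (all-keep/all-flip) also reach accuracy 1,
    # and are counted as ties by the >= rule
    nties <- sum(perm$permAccuracies >= 1)
    expect_equal(perm$p, (1 + nties) / 1001, tolerance = 1e-12)
    expect_gte(perm$p, 1 / 1001)

    # degenerate patterns (conditions identical): every permutation ties
    bim <- matrix(rnorm(8 * 10), 8L)
    wm <- wmFromPatterns(bim, bim + 1e-9)
    psd <- buildPatterns(wm)
    pd <- permutationP(psd, nPerm = 50L, seed = 1)
    expect_identical(pd$p, 1)

    # determinism under a fixed seed
    p1 <- permutationP(ps, nPerm = 100L, seed = 7)
    p2 <- permutationP(ps, nPerm = 100L, seed = 7)
    expect_identical(p1$p, p2$p)
    expect_identical(p1$permAccuracies, p2$permAccuracies)
    expect_error(permutationP(ps, nPerm = 0L, seed = 1), "nPerm")
})

test_that("accuracy is invariant to channel order and affine rescaling", {
    set.seed(23)
    bim <- matrix(rnorm(8 * 46), 8L) + 0.8
    alt <- matrix(rnorm(8 * 46), 8L)
    wm <- wmFromPatterns(bim, alt)
    a0 <- lopoAccuracy(buildPatterns(wm))$accuracy
    # common affine rescale before z-scoring
    wm2 <- wm; wm2$mean <- 3.7 * wm2$mean - 11
    expect_equal(lopoAccuracy(buildPatterns(wm2))$accuracy, a0,
                 tolerance = 1e-12)
    # channel relabelling permutes features only
    perm <- sample(46L)
    wm3 <- wm; wm3$channel <- perm[wm3$channel]
    expect_equal(lopoAccuracy(buildPatterns(wm3))$accuracy, a0,
                 tolerance = 1e-12)
})

test_that("informative channels honour availability, top-30% and symmetry", {
    set.seed(24)
    # 40 of 46 channels sufficiently available -> 12 informative
    bim <- matrix(rnorm(10 * 46), 10L)
    alt <- matrix(rnorm(10 * 46), 10L)
    for (ch in 41:46) { # available for only 60% of participants
        bim[1:4, ch] <- NA; alt[1:4, ch] <- NA
    }
    bim[, c(24L, 27L)] <- bim[, c(24L, 27L)] + 10
    ps <- buildPatterns(wmFromPatterns(bim, alt))
    info <- informativeChannels(ps, availabilityMin = 0.8, topFraction = 0.30)
    expect_identical(length(info$eligible), 40L)
    expect_identical(length(info$channels), 12L) # ceiling(0.3 * 40)
    expect_true(all(c(24L, 27L) %in% info$channels))
    # class symmetry: swapping the labels selects the same channels
    ps2 <- ps
    ps2@labels <- -ps2@labels
    info2 <- informativeChannels(ps2, availabilityMin = 0.8,
                                 topFraction = 0.30)
    expect_setequal(info$channels, info2$channels)
    # no channel available -> error
    psNA <- ps
    psNA@values[] <- NA_real_
    expect_error(informativeChannels(psNA), "availability")
})

test_that("the full decoding wrapper returns a coherent result object", {
    ps <- simulatePatternSet(10, effect = 3, effectChannels = 24:29, seed = 40)
    wm <- wmFromPatterns(
        matrix(ps@values[ps@labels > 0, ], 10L),
        matrix(ps@values[ps@labels < 0, ], 10L))
    d <- decodeConditions(wm, chromophore = "HbO", window = "W2",
                          subset = "all", nPerm = 100L, seed = 3)
    expect_s4_class(d, "NirsDecoding")
    expect_gte(d@accuracy, 0.8)
    expect_lt(d@permP, 0.1)
    expect_identical(d@nPerm, 100L)
    expect_true(all(d@informative %in% 1:46))
    out <- capture.output(show(d))
    expect_true(any(grepl("permutation p", out)))
})
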