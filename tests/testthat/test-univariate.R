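# Explicit design-matrix GLM oracle for the one-group planned contrast:
# regress the per-participant contrast scores on an intercept and F-test it.
contrastOracleGLM <- function(d) {
    fit <- lm(d ~ 1)
    F <- (coef(fit)[[1L]] / sqrt(vcov(fit)[1L, 1L]))^2
    list(F = F, df2 = length(d) - 1L,
         p = pf(F, 1, length(d) - 1L, lower.tail = FALSE))
}

test_that("planned contrast equals the design-matrix oracle", {
    # constructed 6-participant dataset with known window means
    set.seed(5)
    bim <- cbind(rnorm(6), rnorm(6) + 1, rnorm(6) + 0.5)   # baseline, W1, W2
    alt <- cbind(rnorm(6), rnorm(6) + 0.3, rnorm(6) + 0.2)
    wm <- wmFixture(bim, alt, channel = 7L)
    st <- plannedContrast(wm, 7L, "HbO", "W1", "younger")
    d <- (bim[, 2L] - bim[, 1L]) - (alt[, 2L] - alt[, 1L])
    oracle <- contrastOracleGLM(d)
    expect_equal(st$F, oracle$F, tolerance = 1e-8)
    expect_identical(st$df1, 1L)
    expect_identical(st$df2, 5L)
    expect_equal(st$p, oracle$p, tolerance = 1e-8)
    # partial eta^2 from F/dfs matches the SS-based computation on this fit
    ssEffect <- length(d) * mean(d)^2
    ssError <- sum((d - mean(d))^2)
    expect_equal(st$eta_p2, ssEffect / (ssEffect + ssError), tolerance = 1e-10)

    # identical condition means for every participant -> F = 0, p = 1
    same <- cbind(1:6, 1:6 + 2, 1:6 + 1)
    wm0 <- wmFixture(same, same, channel = 2L)
    st0 <- plannedContrast(wm0, 2L, "HbO", "W1", "younger")
    expect_equal(st0$F, 0)
    expect_equal(st0$p, 1)

    # error df follows per-channel complete cases
    wmM <- rbind(wm, wmFixture(bim[1:4, ], alt[1:4, ], channel = 8L,
                 participants = sprintf("p%02d", 1:4)))
    st8 <- plannedContrast(wmM, 8L, "HbO", "W1", "younger")
    expect_identical(st8$df2, 3L)

    # fewer than 2 complete participants: skipped with a message
    wm1 <- wmFixture(bim[1, , drop = FALSE], alt[1, , drop = FALSE],
                     channel = 9L, participants = "p01")
    expect_message(out <- plannedContrast(wm1, 9L, "HbO", "W1", "younger"),
                   "skipped")
    expect_null(out)
})

test_that("with both age groups the contrast reports an age interaction", {
    set.seed(6)
    mkg <- function(n, shift, grp) {
        b <- cbind(rnorm(n), rnorm(n) + shift, rnorm(n))
        a <- cbind(rnorm(n), rnorm(n), rnorm(n))
        wmFixture(b, a, channel = 1L, ageGroup = grp,
                  participants = sprintf("%s%02d", grp, seq_len(n)))
    }
    wm <- rbind(mkg(8, 1.5, "younger"), mkg(8, 0.2, "older"))
    st <- plannedContrast(wm, 1L, "HbO", "W1", "both")
    expect_identical(st$df2, 14L)
    expect_true(all(c("F_age_interaction", "p_age_interaction") %in% names(st)))
    # groups differ by construction: interaction should carry signal
    expect_lt(st$p_age_interaction, 0.2)
})

test_that("post-hoc direction reports the signed condition difference", {
    # uniform 1-uM advantage for bimodal with zero variance: guarded, p ~ 0
    base <- matrix(0, 5L, 3L)
    bim <- base; bim[, 2:3] <- 1
    wm <- wmFixture(bim, base, channel = 3L)
    ph <- posthocCondition(wm, 3L, "HbO", "W2", "younger")
    expect_identical(ph$direction, "bimodal>alternating")
    expect_lt(ph$p, 1e-3)

    # near-balanced differences: p well above 0.5, exact paired-t oracle
    diffs <- c(1, -1, 1, -1, 1, -1, 0.05, -0.01)
    bim2 <- cbind(0, diffs, 0)
    alt2 <- cbind(0, 0 * diffs, 0)
    wm2 <- wmFixture(bim2, alt2, channel = 4L)
    ph2 <- posthocCondition(wm2, 4L, "HbO", "W1", "younger")
    tt <- t.test(diffs)
    expect_equal(ph2$p, tt$p.value, tolerance = 1e-10)
    expect_gt(ph2$p, 0.5)

    # direction is reported even when non-significant
    expect_identical(ph2$direction, "bimodal>alternating")
})

test_that("FDR adjustment matches a brute-force step-up oracle", {
    expect_identical(fdrAdjust(0.03), 0.03)
    expect_identical(fdrAdjust(numeric(0)), numeric(0))
    expect_true(all(fdrAdjust(rep(0.01, 46)) < 0.05))
    set.seed(7)
    for (r in 1:20) {
        p <- runif(sample(3:60, 1L))^sample(1:3, 1L)
        expect_equal(fdrAdjust(p), bhStepUpOracle(p), tolerance = 1e-12)
    }
})

test_that("additivity labels follow the chromophore-dependent mapping", {
    expect_identical(labelAdditivity("HbO", "bimodal>alternating", TRUE), "super")
    expect_identical(labelAdditivity("HbO", "alternating>bimodal", TRUE), "sub")
    expect_identical(labelAdditivity("HbR", "bimodal>alternating", TRUE), "sub")
    expect_identical(labelAdditivity("HbR", "alternating>bimodal", TRUE), "super")
    expect_identical(labelAdditivity("HbO", "bimodal>alternating", FALSE), "none")
    expect_identical(labelAdditivity("HbR", "none", TRUE), "none")
    # vectorised
    expect_identical(
        labelAdditivity(c("HbO", "HbR"),
                        c("bimodal>alternating", "bimodal>alternating"),
                        c(TRUE, TRUE)),
        c("super", "sub"))
})

test_that("channel table aggregates contrasts, FDR families and labels", {
    set.seed(8)
    wm <- do.call(rbind, lapply(1:46, function(ch) {
        shift <- if (ch %in% c(24L, 26L)) 4 else 0
        wmFixture(cbind(rnorm(10), rnorm(10) + shift, rnorm(10) + shift),
                  cbind(rnorm(10), rnorm(10), rnorm(10)), channel = ch)
    }))
    cs <- channelStats(wm, ageGroup = "younger")
    expect_identical(nrow(cs), 46L * 2L) # one chromophore in fixture x 2 windows
    expect_true(all(cs$chromophore == "HbO"))
    # planted channels significant and labelled super, FDR-flagged
    planted <- cs[cs$channel %in% c(24L, 26L), ]
    expect_true(all(planted$significant))
    expect_true(all(planted$label == "super"))
    expect_true(all(planted$fdr_significant))
    # FDR family = channels within chromophore x window
    w1 <- cs[cs$window == "W1", ]
    expect_equal(w1$p_fdr, fdrAdjust(w1$p), tolerance = 1e-12)
    # hemisphere/region annotation from the montage
    expect_identical(unique(planted$hemisphere), "right")
    expect_identical(unique(planted$region), "inferior_frontal")
    # agreement between the table and the single-channel operations
    st <- plannedContrast(wm, 24L, "HbO", "W1", "younger")
    row <- cs[cs$channel == 24L & cs$window == "W1", ]
    expect_equal(row$F, st$F, tolerance = 1e-10)
    ph <- posthocCondition(wm, 24L, "HbO", "W1", "younger")
    expect_equal(row$posthoc_p, ph$p, tolerance = 1e-10)
})
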