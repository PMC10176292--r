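#' Build across-participant activation patterns
#'
#' Extracts, for one chromophore and activation window, each participant's
#' channel-indexed mean-activation vector per condition, restricts the
#' channels to a hemisphere subset if requested, and z-scores every channel
#' across all patterns (both conditions, all participants, non-missing
#' entries) so channels are on comparable scales for classification.
#' Channels a participant did not contribute stay `NA`; they are never
#' imputed.  Channels with zero variance are dropped with a warning
#' (normalization undefined), as are channels missing everywhere.
#'
#' @param wm a window-means table from included participants.
#' @param montage a [NirsMontage-class].
#' @param chromophore `"HbO"` or `"HbR"`.
#' @param window `"W1"` or `"W2"`.
#' @param subset `"all"`, `"left"` or `"right"` hemisphere channels.
#' @param ageGroup restrict to one age group (`NULL` keeps all participants).
#' @param prepandemicOnly keep only participants tested before the pandemic
#'   cutoff.
#' @return a [NirsPatternSet-class].
#' @export
buildPatterns <- function(wm, montage = defaultMontage(), chromophore = "HbO",
                          window = "W2", subset = c("all", "left", "right"),
                          ageGroup = NULL, prepandemicOnly = FALSE) {
    subset <- match.arg(subset)
    sub <- wm[wm$chromophore == chromophore & wm$window == window, , drop = FALSE]
    if (!is.null(ageGroup)) sub <- sub[sub$age_group == ageGroup, , drop = FALSE]
    if (prepandemicOnly) sub <- sub[sub$prepandemic, , drop = FALSE]
    chans <- if (subset == "all") 1:46 else hemisphereChannels(montage, subset)
    sub <- sub[sub$channel %in% chans, , drop = FALSE]
    parts <- unique(sub$participant)
    if (!length(parts)) stop("no participants available for this pattern set")

    n <- length(parts)
    M <- matrix(NA_real_, 2L * n, length(chans),
                dimnames = list(NULL, as.character(chans)))
    labels <- numeric(2L * n)
    pid <- character(2L * n)
    for (i in seq_len(n)) {
        for (k in 1:2) {
            cc <- .CONDITIONS[k]
            r <- 2L * (i - 1L) + k
            rows <- sub[sub$participant == parts[i] & sub$condition == cc, ]
            M[r, as.character(rows$channel)] <- rows$mean
            labels[r] <- if (cc == "bimodal") 1 else -1
            pid[r] <- parts[i]
        }
    }
    allNA <- colSums(!is.na(M)) == 0L
    zeroVar <- !allNA & apply(M, 2L, function(x) stats::sd(x, na.rm = TRUE) == 0)
    if (any(zeroVar))
        warning(sprintf("dropping zero-variance channel(s): %s",
                paste(colnames(M)[zeroVar], collapse = ", ")))
    M <- M[, !(allNA | zeroVar), drop = FALSE]
    mu <- colMeans(M, na.rm = TRUE)
    sdv <- apply(M, 2L, stats::sd, na.rm = TRUE)
    M <- sweep(sweep(M, 2L, mu), 2L, sdv, "/")

    new("NirsPatternSet", values = M, labels = labels, participants = pid,
        channels = as.integer(colnames(M)), subset = subset,
        chromophore = chromophore, window = window,
        ageGroup = if (is.null(ageGroup)) "all" else ageGroup)
}

.partIndex <- function(ps) {
    match(ps@participants, unique(ps@participants))
}

#' Leave-one-participant-out decoding accuracy
#'
#' Per fold, all training and test patterns are restricted to the held-out
#' participant's available channels (by default further intersected with the
#' channels available for every training pattern, so the fold's feature space
#' is complete); a linear maximum-margin classifier (soft margin, fixed
#' `cost`) is trained on the `2(N-1)` remaining condition-average patterns
#' and predicts the held-out participant's two patterns.  Accuracy is the
#' proportion of correct labels over all predictions.  Folds without a single
#' usable channel are skipped.
#'
#' @param patterns a [NirsPatternSet-class].
#' @param cost soft-margin cost parameter (fixed at 1 by default; no tuning,
#'   which would leak across folds).
#' @param maskRule `"intersection"` (default) or `"test"`: with `"test"` the
#'   fold keeps all channels available for the held-out participant and drops
#'   training participants missing any of them.
#' @return list with `accuracy` (per-pattern), `accuracyBothCorrect`
#'   (proportion of participants with both patterns correct), `folds`
#'   (per-pattern predictions) and `nFolds`.
#' @export
lopoAccuracy <- function(patterns, cost = 1,
                         maskRule = c("intersection", "test")) {
    maskRule <- match.arg(maskRule)
    if (length(unique(patterns@participants)) < 3L)
        stop("leave-one-participant-out needs at least 3 participants")
    r <- .lopo_cpp(patterns@values, .partIndex(patterns), patterns@labels,
                   cost, maskRule == "intersection")
    pred <- ifelse(is.na(r$pred), NA_character_,
                   ifelse(r$pred > 0, "bimodal", "alternating"))
    truth <- ifelse(patterns@labels > 0, "bimodal", "alternating")
    folds <- data.frame(participant = patterns@participants,
        condition = truth, predicted = pred,
        correct = !is.na(pred) & pred == truth)
    both <- tapply(folds$correct, patterns@participants, all)
    evaluated <- !is.na(pred)
    list(accuracy = r$accuracy,
         accuracyBothCorrect = mean(both[unique(patterns@participants) %in%
             unique(patterns@participants[evaluated])]),
         folds = folds, nFolds = r$n_folds)
}

#' Permutation test of decoding accuracy
#'
#' Builds the empirical null by retraining the whole leave-one-participant-out
#' analysis under permuted labels: per permutation, every participant's two
#' condition labels are independently either kept or exchanged (fair coin).
#' The inclusive estimator counts the observed accuracy in both numerator and
#' denominator, `p = (1 + #(permuted >= observed)) / (1 + n_perm)`, so ties
#' count against the observed value and an accuracy above all 1000 permuted
#' accuracies gives exactly `1/1001`.
#'
#' @inheritParams lopoAccuracy
#' @param nPerm number of permutations (1000 in the canonical analysis).
#' @param seed integer seed for the permutation draws.
#' @return list with `p`, `observed`, `permAccuracies`, `nPerm`.
#' @export
permutationP <- function(patterns, nPerm = 1000L, seed = 1L, cost = 1,
                         maskRule = c("intersection", "test")) {
    maskRule <- match.arg(maskRule)
    if (nPerm < 1L) stop("nPerm must be at least 1")
    part <- .partIndex(patterns)
    obs <- .lopo_cpp(patterns@values, part, patterns@labels, cost,
                     maskRule == "intersection")$accuracy
    npart <- max(part)
    set.seed(seed)
    flips <- matrix(stats::runif(nPerm * npart) < 0.5, nPerm, npart)
    acc <- .perm_lopo_cpp(patterns@values, part, patterns@labels, cost,
                          maskRule == "intersection", flips)
    p <- (1 + sum(acc >= obs, na.rm = TRUE)) / (1 + nPerm)
    list(p = p, observed = obs, permAccuracies = acc, nPerm = as.integer(nPerm))
}

#' Informative channels of the final model
#'
#' Retrains the classifier on the two grand-average (across participants)
#' condition patterns, using only channels with usable data in at least
#' `availabilityMin` of participants, and scores each channel by the product
#' of its weight and grand-average pattern value.  The informative set is the
#' `topFraction` most extreme scores (ceiling; ties at the boundary are all
#' included).  Because the z-scored class averages are sign-symmetric, the
#' set for the positive class equals the set for the negative class.
#'
#' @inheritParams lopoAccuracy
#' @param availabilityMin minimum fraction of participants with usable data
#'   (default 0.8).
#' @param topFraction fraction of eligible channels reported (default 0.30).
#' @return list with `weights`, `scores` (named by channel), `channels`
#'   (informative ids), `eligible` (ids entering the final model).
#' @export
informativeChannels <- function(patterns, availabilityMin = 0.8,
                                topFraction = 0.30, cost = 1) {
    M <- patterns@values
    part <- .partIndex(patterns)
    npart <- max(part)
    availByPart <- rowsum((!is.na(M)) + 0, part) == 2L
    avail <- colSums(availByPart) / npart
    keep <- avail >= availabilityMin
    if (!any(keep)) stop("no channel reaches the availability threshold")
    Mk <- M[, keep, drop = FALSE]
    gA <- colMeans(Mk[patterns@labels < 0, , drop = FALSE], na.rm = TRUE)
    gB <- colMeans(Mk[patterns@labels > 0, , drop = FALSE], na.rm = TRUE)
    fit <- .svm_linear_cpp(rbind(gB, gA), c(1, -1), cost)
    scores <- fit$w * gB
    names(scores) <- colnames(Mk)
    k <- ceiling(topFraction * length(scores))
    thr <- sort(abs(scores), decreasing = TRUE)[k]
    sel <- abs(scores) >= thr
    list(weights = stats::setNames(fit$w, colnames(Mk)), scores = scores,
         channels = patterns@channels[keep][sel],
         eligible = patterns@channels[keep])
}

#' Full decoding analysis for one chromophore, window and channel subset
#'
#' Convenience wrapper: builds the pattern set, runs the
#' leave-one-participant-out accuracy, the permutation test and the
#' informative-channel model, and returns a [NirsDecoding-class].
#'
#' @inheritParams buildPatterns
#' @inheritParams permutationP
#' @inheritParams informativeChannels
#' @export
decodeConditions <- function(wm, montage = defaultMontage(),
                             chromophore = "HbO", window = "W2",
                             subset = "all", ageGroup = NULL,
                             prepandemicOnly = FALSE,
                             nPerm = 1000L, seed = 1L, cost = 1,
                             maskRule = "intersection",
                             availabilityMin = 0.8, topFraction = 0.30) {
    ps <- buildPatterns(wm, montage, chromophore, window, subset, ageGroup,
                        prepandemicOnly)
    acc <- lopoAccuracy(ps, cost, maskRule)
    perm <- permutationP(ps, nPerm, seed, cost, maskRule)
    info <- informativeChannels(ps, availabilityMin, topFraction, cost)
    new("NirsDecoding", accuracy = acc$accuracy,
        accuracyBothCorrect = acc$accuracyBothCorrect,
        folds = acc$folds, nFolds = as.integer(acc$nFolds),
        permP = perm$p, nPerm = perm$nPerm, permAccuracies = perm$permAccuracies,
        weights = info$weights, scores = info$scores,
        informative = as.integer(info$channels),
        subset = subset, chromophore = chromophore, window = window,
        ageGroup = if (is.null(ageGroup)) "all" else ageGroup)
}

setMethod("show", "NirsDecoding", function(object) {
    cat(sprintf("NirsDecoding: %s, %s, %s channels, %s group\n",
        object@chromophore, object@window, object@subset, object@ageGroup))
    cat(sprintf("  LOPO accuracy %.3f (%d folds; both-patterns-correct %.3f)\n",
        object@accuracy, object@nFolds, object@accuracyBothCorrect))
    cat(sprintf("  permutation p = %.4g (%d permutations, inclusive)\n",
        object@permP, object@nPerm))
    cat("  informative channels:", paste(object@informative, collapse = ", "), "\n")
})
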