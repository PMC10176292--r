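# Wide per-participant extraction for one channel/chromophore: baseline and
# activation-window means for both conditions, complete cases only.
.contrastData <- function(wm, channel, chromophore, window, ageGroup) {
    sub <- wm[wm$channel == channel & wm$chromophore == chromophore, , drop = FALSE]
    if (!identical(ageGroup, "both"))
        sub <- sub[sub$age_group == ageGroup, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    need <- expand.grid(condition = .CONDITIONS, window = c("baseline", window),
                        stringsAsFactors = FALSE)
    pick <- function(p, cc, w) {
        v <- sub$mean[sub$participant == p & sub$condition == cc & sub$window == w]
        if (length(v) == 1L) v else NA_real_
    }
    parts <- unique(sub$participant)
    M <- vapply(parts, function(p)
        mapply(pick, p, need$condition, need$window), numeric(nrow(need)))
    cc <- which(colSums(is.na(M)) == 0L)
    if (!length(cc)) return(NULL)
    d <- (M[3L, cc] - M[1L, cc]) - (M[4L, cc] - M[2L, cc]) # (W-B)bim - (W-B)alt
    act <- M[3L, cc] - M[4L, cc]                           # bimodal - alternating, in-window
    grp <- vapply(cc, function(j)
        sub$age_group[sub$participant == parts[j]][1L], "")
    list(participants = parts[cc], d = d, act = act, group = grp)
}

.contrastF <- function(d) {
    n <- length(d)
    v <- max(stats::var(d), .Machine$double.eps)
    F <- n * mean(d)^2 / v
    df2 <- n - 1L
    list(F = F, df1 = 1L, df2 = df2,
         p = stats::pf(F, 1L, df2, lower.tail = FALSE),
         eta = F / (F + df2), n = n)
}

#' Planned simple contrast for one channel
#'
#' Tests, per channel, whether the baseline-to-activation change differs
#' between the two conditions: within an age group, the per-participant
#' contrast score `d = (window - baseline)_bimodal - (window -
#' baseline)_alternating` is tested against zero as a 1-df contrast F
#' (the squared paired t), with error df `n - 1` from the channel's complete
#' cases.  With `ageGroup = "both"`, age enters as a between factor: the
#' contrast F tests the unweighted grand mean of `d` and the age x contrast
#' interaction is reported alongside, both on `N - 2` error df.  Partial eta
#' squared is `F df1 / (F df1 + df2)`.
#'
#' @param wm a window-means table (see [windowMeans()]).
#' @param channel channel id.
#' @param chromophore `"HbO"` or `"HbR"`.
#' @param window `"W1"` (5-10 s) or `"W2"` (10-15 s).
#' @param ageGroup `"younger"`, `"older"` or `"both"`.
#' @return one-row `data.frame` (`F`, `df1`, `df2`, `p`, `eta_p2`, `n`, and
#'   for `"both"` also `F_age_interaction`, `p_age_interaction`), or `NULL`
#'   when fewer than two complete participants exist (skipped, with a
#'   message).
#' @export
plannedContrast <- function(wm, channel, chromophore = "HbO", window = "W2",
                            ageGroup = "younger") {
    dat <- .contrastData(wm, channel, chromophore, window, ageGroup)
    if (is.null(dat) || length(dat$d) < 2L) {
        message(sprintf("channel %d: fewer than 2 complete participants, skipped",
                        channel))
        return(NULL)
    }
    if (identical(ageGroup, "both") && length(unique(dat$group)) == 2L) {
        g <- factor(dat$group)
        n1 <- sum(g == levels(g)[1L]); n2 <- sum(g == levels(g)[2L])
        if (n1 < 2L || n2 < 2L) return(NULL)
        m <- tapply(dat$d, g, mean)
        s2 <- (sum((dat$d - m[g])^2)) / (n1 + n2 - 2L)
        s2 <- max(s2, .Machine$double.eps)
        df2 <- n1 + n2 - 2L
        Fg <- (mean(m))^2 / (s2 / 4 * (1 / n1 + 1 / n2))
        Fi <- (m[1L] - m[2L])^2 / (s2 * (1 / n1 + 1 / n2))
        return(data.frame(channel = channel, chromophore = chromophore,
            window = window, age_group = "both",
            F = unname(Fg), df1 = 1L, df2 = df2,
            p = stats::pf(unname(Fg), 1L, df2, lower.tail = FALSE),
            eta_p2 = unname(Fg) / (unname(Fg) + df2), n = n1 + n2,
            F_age_interaction = unname(Fi),
            p_age_interaction = stats::pf(unname(Fi), 1L, df2, lower.tail = FALSE)))
    }
    ct <- .contrastF(dat$d)
    data.frame(channel = channel, chromophore = chromophore, window = window,
        age_group = ageGroup, F = ct$F, df1 = ct$df1, df2 = ct$df2, p = ct$p,
        eta_p2 = ct$eta, n = ct$n)
}

#' Post-hoc condition comparison within an activation window
#'
#' Paired comparison of the two conditions' window means (paired t), giving
#' the signed direction of the difference and its p value.  The direction is
#' always reported; whether a super/sub-additivity label is attached is
#' decided downstream by significance.
#'
#' @inheritParams plannedContrast
#' @return list with `direction` (`"bimodal>alternating"`,
#'   `"alternating>bimodal"` or `"none"`), `p`, `mean_diff`, `n`.
#' @export
posthocCondition <- function(wm, channel, chromophore = "HbO", window = "W2",
                             ageGroup = "younger") {
    dat <- .contrastData(wm, channel, chromophore, window, ageGroup)
    if (is.null(dat) || length(dat$act) < 2L) return(NULL)
    x <- dat$act
    n <- length(x)
    se <- sqrt(max(stats::var(x), .Machine$double.eps) / n)
    tstat <- mean(x) / se
    p <- 2 * stats::pt(abs(tstat), n - 1L, lower.tail = FALSE)
    dir <- if (mean(x) > 0) "bimodal>alternating"
        else if (mean(x) < 0) "alternating>bimodal" else "none"
    list(direction = dir, p = p, mean_diff = mean(x), n = n)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values; the family is all channels within one
#' chromophore x window x age-group analysis.
#'
#' @param p numeric vector of p values.
#' @return adjusted p values, same length.
#' @export
fdrAdjust <- function(p) {
    stats::p.adjust(p, method = "BH")
}

#' Label a significant condition difference as super- or sub-additive
#'
#' The multisensory interpretation depends on the chromophore: a larger HbO
#' increase to the bimodal condition is consistent with super-additivity and
#' a larger HbO increase to the alternating condition with sub-additivity;
#' for HbR the mapping inverts (a larger HbR increase to bimodal is
#' sub-additive, to alternating super-additive).  Non-significant contrasts
#' are labelled `"none"`.
#'
#' @param chromophore `"HbO"` or `"HbR"` (vectorised).
#' @param direction `"bimodal>alternating"`, `"alternating>bimodal"` or
#'   `"none"`.
#' @param significant logical.
#' @return character vector of `"super"`, `"sub"`, `"none"`.
#' @export
labelAdditivity <- function(chromophore, direction, significant) {
    mapply(function(chrom, dir, sig) {
        if (!isTRUE(sig) || dir == "none") return("none")
        if (chrom == "HbO") {
            if (dir == "bimodal>alternating") "super" else "sub"
        } else {
            if (dir == "bimodal>alternating") "sub" else "super"
        }
    }, chromophore, direction, significant, USE.NAMES = FALSE)
}

#' Channel-by-channel planned-contrast table
#'
#' Runs the planned contrast, post-hoc direction, FDR adjustment (within each
#' chromophore x window family) and additivity labelling over all channels,
#' producing the result-table layout used for reporting (chromophore,
#' hemisphere, region, channel, time window, F, dfs, p, partial eta squared,
#' post-hoc p, direction, label, FDR flag).
#'
#' @param wm a window-means table.
#' @param montage a [NirsMontage-class] (hemisphere/region annotation).
#' @param chromophores,windows which analyses to run.
#' @param ageGroup `"younger"`, `"older"` or `"both"`.
#' @param alpha significance level for labelling (default 0.05, uncorrected,
#'   with the FDR flag carried alongside).
#' @param channels channel ids to analyse (default all 46).
#' @return `data.frame`, one row per channel x chromophore x window with a
#'   computable contrast.
#' @export
channelStats <- function(wm, montage = defaultMontage(),
                         chromophores = .CHROMOPHORES, windows = c("W1", "W2"),
                         ageGroup = "younger", alpha = 0.05, channels = 1:46) {
    ch <- channelTable(montage)
    channels <- as.integer(channels)
    sub <- if (identical(ageGroup, "both")) wm else
        wm[wm$age_group == ageGroup, , drop = FALSE]
    if (!nrow(sub)) return(data.frame())
    # one pivot: participant x channel x condition x window x chromophore
    # (keys are unique in a window-means table, so direct assignment suffices)
    parts <- sort(unique(sub$participant))
    arr <- array(NA_real_, c(length(parts), 46L, 2L, 3L, 2L),
        dimnames = list(parts, 1:46, .CONDITIONS, .WINDOWS, .CHROMOPHORES))
    arr[cbind(match(sub$participant, parts), sub$channel,
              match(sub$condition, .CONDITIONS),
              match(sub$window, .WINDOWS),
              match(sub$chromophore, .CHROMOPHORES))] <- sub$mean
    out <- list()
    for (chrom in chromophores) {
        for (w in windows) {
            acc <- list()
            for (cid in channels) {
                B <- arr[, cid, "bimodal", c("baseline", w), chrom, drop = TRUE]
                A <- arr[, cid, "alternating", c("baseline", w), chrom, drop = TRUE]
                if (length(parts) == 1L) { B <- rbind(B); A <- rbind(A) }
                ok <- rowSums(is.na(cbind(B, A))) == 0L
                if (sum(ok) < 2L) next
                d <- (B[ok, 2L] - B[ok, 1L]) - (A[ok, 2L] - A[ok, 1L])
                if (identical(ageGroup, "both")) {
                    st <- suppressMessages(
                        plannedContrast(wm, cid, chrom, w, ageGroup))
                    if (is.null(st)) next
                    stats_row <- c(st$F, st$df1, st$df2, st$p, st$eta_p2, st$n)
                } else {
                    ct <- .contrastF(d)
                    stats_row <- c(ct$F, ct$df1, ct$df2, ct$p, ct$eta, ct$n)
                }
                act <- B[ok, 2L] - A[ok, 2L]
                se <- sqrt(max(stats::var(act), .Machine$double.eps) /
                           length(act))
                php <- 2 * stats::pt(abs(mean(act) / se), length(act) - 1L,
                                     lower.tail = FALSE)
                dir <- if (mean(act) > 0) "bimodal>alternating"
                    else if (mean(act) < 0) "alternating>bimodal" else "none"
                acc[[length(acc) + 1L]] <- list(cid, stats_row, php, dir)
            }
            if (!length(acc)) next
            sm <- do.call(rbind, lapply(acc, `[[`, 2L))
            tab <- data.frame(
                channel = vapply(acc, `[[`, 0L, 1L),
                chromophore = chrom, window = w, age_group = ageGroup,
                F = sm[, 1L], df1 = as.integer(sm[, 2L]),
                df2 = as.integer(sm[, 3L]), p = sm[, 4L], eta_p2 = sm[, 5L],
                n = as.integer(sm[, 6L]),
                posthoc_p = vapply(acc, `[[`, 0, 3L),
                direction = vapply(acc, `[[`, "", 4L))
            tab$p_fdr <- fdrAdjust(tab$p)
            tab$fdr_significant <- tab$p_fdr < alpha
            tab$significant <- tab$p < alpha
            tab$label <- labelAdditivity(tab$chromophore, tab$direction,
                                         tab$significant)
            out[[length(out) + 1L]] <- tab
        }
    }
    if (!length(out))
        return(data.frame())
    res <- do.call(rbind, out)
    res$hemisphere <- ch$hemisphere[res$channel]
    res$region <- ch$region[res$channel]
    rownames(res) <- NULL
    res[, c("chromophore", "hemisphere", "region", "channel", "window",
            "age_group", "F", "df1", "df2", "p", "eta_p2", "posthoc_p",
            "direction", "label", "significant", "p_fdr", "fdr_significant",
            "n")]
}
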