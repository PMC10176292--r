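#' @import methods
#' @importFrom S4Vectors metadata metadata<- SimpleList DataFrame
NULL

.CONDITIONS <- c("bimodal", "alternating")
.ALL_CONDITIONS <- c(.CONDITIONS, "baseline")
.CHROMOPHORES <- c("HbO", "HbR")
.REGIONS <- c("inferior_frontal", "superior_temporal", "other")
.WINDOWS <- c("baseline", "W1", "W2")

#' Optode montage for a 46-channel infant fNIRS array
#'
#' An S4 container for the measurement-channel layout: source/detector pairing,
#' hemisphere, anatomical region tag (inferior frontal, superior temporal or
#' other), channel adjacency and source-detector separation.  All downstream
#' stages (Beer-Lambert conversion, hemisphere-restricted decoding, region
#' summaries in result tables) consume the montage rather than raw channel ids.
#'
#' @slot channels `data.frame` with one row per channel and columns
#'   `id` (integer, 1-46), `source_id`, `detector_id`, `hemisphere`
#'   (`"left"`/`"right"`), `region`, and `separation_cm`.
#' @slot adjacency named `list`; element `"<id>"` holds the integer ids of the
#'   spatially neighbouring channels.  Symmetric.
#'
#' @seealso [defaultMontage()]
#' @export
setClass("NirsMontage",
    representation(channels = "data.frame", adjacency = "list"))

setValidity("NirsMontage", function(object) {
    ch <- object@channels
    msg <- character()
    need <- c("id", "source_id", "detector_id", "hemisphere", "region", "separation_cm")
    if (!all(need %in% names(ch)))
        return(paste("channels must have columns:", paste(need, collapse = ", ")))
    if (nrow(ch) != 46L || !identical(sort(as.integer(ch$id)), 1:46))
        msg <- c(msg, "montage must define exactly channels 1..46")
    if (!all(ch$hemisphere %in% c("left", "right")))
        msg <- c(msg, "every channel needs hemisphere 'left' or 'right'")
    if (!all(ch$region %in% .REGIONS))
        msg <- c(msg, paste("region must be one of:", paste(.REGIONS, collapse = ", ")))
    if (any(ch$separation_cm <= 0))
        msg <- c(msg, "source-detector separation must be > 0")
    adj <- object@adjacency
    if (!identical(sort(names(adj)), sort(as.character(ch$id)))) {
        msg <- c(msg, "adjacency must be named by channel id")
    } else {
        for (id in names(adj)) {
            for (nb in adj[[id]]) {
                if (!as.integer(id) %in% adj[[as.character(nb)]]) {
                    msg <- c(msg, "adjacency must be symmetric")
                    break
                }
            }
        }
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Raw dual-wavelength fNIRS recording
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with channels as rows
#' and time samples as columns.  Two assays, `"wl780"` and `"wl850"`, hold the
#' raw light intensities (arbitrary units) at the 780 nm and 850 nm source
#' wavelengths.  `rowData` carries the montage channel annotation plus the
#' `usable` pruning flag; experiment-level metadata holds the participant id,
#' age group, sampling rate, the event schedule and the per-trial looking
#' proportions.
#'
#' Use the [NirsRecording()] constructor rather than `new()`.
#'
#' @seealso [NirsRecording()], [readRecording()], [simulateCohort()]
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("NirsRecording", contains = "SummarizedExperiment")

.validEvents <- function(ev) {
    need <- c("condition", "onset_s", "duration_s")
    if (!is.data.frame(ev) || !all(need %in% names(ev)))
        return("events must be a data.frame with columns condition, onset_s, duration_s")
    if (!all(ev$condition %in% .ALL_CONDITIONS))
        return(paste("event conditions must be among:", paste(.ALL_CONDITIONS, collapse = ", ")))
    if (nrow(ev) > 1L) {
        if (is.unsorted(ev$onset_s))
            return("events must be ordered by onset time")
        ends <- ev$onset_s + ev$duration_s
        if (any(ev$onset_s[-1L] < ends[-nrow(ev)] - 1e-9))
            return("events must not overlap")
    }
    TRUE
}

setValidity("NirsRecording", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("wl780", "wl850") %in% an))
        return("recording needs intensity assays 'wl780' and 'wl850' (two wavelengths per channel)")
    if (nrow(object) != 46L)
        msg <- c(msg, sprintf("recording must carry 46 channels, found %d", nrow(object)))
    for (a in c("wl780", "wl850")) {
        v <- SummarizedExperiment::assay(object, a)
        if (any(v < 0, na.rm = TRUE))
            msg <- c(msg, sprintf("assay '%s' has negative intensities", a))
    }
    md <- metadata(object)
    if (is.null(md$sampling_rate) || md$sampling_rate <= 0)
        msg <- c(msg, "sampling_rate must be a positive scalar (Hz)")
    if (is.null(md$age_group) || !md$age_group %in% c("younger", "older"))
        msg <- c(msg, "age_group must be 'younger' or 'older'")
    evok <- .validEvents(md$events)
    if (!isTRUE(evok)) msg <- c(msg, evok)
    if (isTRUE(evok)) {
        nstim <- sum(md$events$condition %in% .CONDITIONS)
        if (length(md$looking) != nstim)
            msg <- c(msg, sprintf(
                "need one looking proportion per stimulation trial (%d trials, %d values)",
                nstim, length(md$looking)))
        if (any(md$looking < 0 | md$looking > 1))
            msg <- c(msg, "looking proportions must lie in [0, 1]")
    }
    if (!"usable" %in% names(SummarizedExperiment::rowData(object)))
        msg <- c(msg, "rowData must carry the 'usable' channel flag")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Epoched concentration data with rejection flags
#'
#' Per-trial haemoglobin-concentration segments cut around stimulation onsets
#' (-5 s to +20 s), together with the bookkeeping the inclusion rules produce:
#' per-channel motion-rejection flags, channel exclusions, looking-based trial
#' rejections and the participant-level inclusion verdict.
#'
#' @slot values numeric array `[time, trial, channel, chromophore]`, micromolar.
#' @slot time numeric vector of epoch times (seconds relative to onset).
#' @slot trials `data.frame` with one row per stimulation trial: `condition`,
#'   `onset_s`, `looking`, `looking_rejected`, `past_end`, `motion_rejected`
#'   (any usable channel hit) and `surviving`.
#' @slot motionRejected logical matrix `[trial, channel]`.
#' @slot channelUsable logical, channels usable after pruning and the
#'   excessive-artifact rule.
#' @slot participant,ageGroup participant annotation.
#' @slot included logical participant verdict; @slot exclusionReason one of
#'   `"none"`, `"channels"`, `"trials"`, `"channels+trials"`.
#' @export
setClass("NirsEpochs",
    representation(values = "array", time = "numeric", trials = "data.frame",
        motionRejected = "matrix", channelUsable = "logical",
        participant = "character", ageGroup = "character",
        included = "logical", exclusionReason = "character"))

setValidity("NirsEpochs", function(object) {
    d <- dim(object@values)
    msg <- character()
    if (length(d) != 4L)
        return("values must be a 4-d array [time, trial, channel, chromophore]")
    if (d[1L] != length(object@time))
        msg <- c(msg, "time grid must match the first array dimension")
    if (d[2L] != nrow(object@trials))
        msg <- c(msg, "trial table must match the second array dimension")
    if (!identical(dim(object@motionRejected), d[2:3]))
        msg <- c(msg, "motionRejected must be trial x channel")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Across-participant activation patterns for decoding
#'
#' One channel-indexed pattern per participant and condition (a single
#' chromophore and analysis window), z-scored within channel across all
#' participants and conditions.  Missing channels are `NA`, never imputed.
#'
#' @slot values numeric matrix, `2 N x channels`; rows alternate the two
#'   conditions within participant.
#' @slot labels numeric vector in `{-1, +1}` (+1 = bimodal).
#' @slot participants character vector parallel to the rows.
#' @slot channels integer channel ids (column order).
#' @slot subset,chromophore,window,ageGroup analysis annotation.
#' @export
setClass("NirsPatternSet",
    representation(values = "matrix", labels = "numeric", participants = "character",
        channels = "integer", subset = "character", chromophore = "character",
        window = "character", ageGroup = "character"))

setValidity("NirsPatternSet", function(object) {
    msg <- character()
    if (nrow(object@values) != length(object@labels) ||
        nrow(object@values) != length(object@participants))
        msg <- c(msg, "rows, labels and participants must be parallel")
    if (!all(object@labels %in% c(-1, 1)))
        msg <- c(msg, "labels must be coded -1/+1")
    tab <- table(object@participants)
    if (length(tab) && !all(tab == 2L))
        msg <- c(msg, "each participant must contribute exactly two patterns (balanced)")
    if (ncol(object@values) != length(object@channels))
        msg <- c(msg, "channel ids must match the columns")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Result of a leave-one-participant-out decoding analysis
#'
#' @slot accuracy proportion of correctly labelled patterns (per-pattern
#'   counting).
#' @slot accuracyBothCorrect proportion of participants with both patterns
#'   correct (the stricter participant-level counter).
#' @slot folds per-pattern predictions.
#' @slot nFolds number of folds actually evaluated.
#' @slot permP inclusive permutation p value; @slot nPerm permutations used;
#'   @slot permAccuracies the permutation null distribution.
#' @slot weights final-model channel weights (channels with at least the
#'   required availability); @slot scores weight x grand-average products;
#'   @slot informative ids of the most informative channels (top 30 percent,
#'   ties included).
#' @slot subset,chromophore,window,ageGroup analysis annotation.
#' @export
setClass("NirsDecoding",
    representation(accuracy = "numeric", accuracyBothCorrect = "numeric",
        folds = "data.frame", nFolds = "integer",
        permP = "numeric", nPerm = "integer", permAccuracies = "numeric",
        weights = "numeric", scores = "numeric", informative = "integer",
        subset = "character", chromophore = "character", window = "character",
        ageGroup = "character"))

setValidity("NirsDecoding", function(object) {
    msg <- character()
    if (length(object@accuracy) == 1L && !is.na(object@accuracy) &&
        (object@accuracy < 0 || object@accuracy > 1))
        msg <- c(msg, "accuracy must lie in [0, 1]")
    if (length(object@permP) == 1L && !is.na(object@permP) &&
        (object@permP <= 0 || object@permP > 1))
        msg <- c(msg, "permutation p must lie in (0, 1]")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
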