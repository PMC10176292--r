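#' Construct a raw fNIRS recording
#'
#' @param wl780,wl850 numeric matrices, channel x time, raw intensities at the
#'   two source wavelengths (arbitrary units, non-negative).
#' @param montage a [NirsMontage-class]; defaults to [defaultMontage()].
#' @param samplingRate sampling rate in Hz.
#' @param events `data.frame` with columns `condition`
#'   (`"bimodal"`/`"alternating"`/`"baseline"`), `onset_s`, `duration_s`;
#'   time-ordered and non-overlapping.
#' @param looking numeric vector, one proportion in `[0, 1]` per stimulation
#'   trial (time spent looking at the screen).
#' @param participantId,ageGroup participant annotation; `ageGroup` is
#'   `"younger"` (5-6 months) or `"older"` (9-10 months).
#' @param usable logical length-46 channel usability flag (filled by
#'   [pruneChannels()]; defaults to all `TRUE`).
#' @param prepandemic logical scalar, `TRUE` for participants tested before
#'   the pandemic cutoff (used by the exploratory subset analyses).
#' @return A validated [NirsRecording-class].
#' @export
NirsRecording <- function(wl780, wl850, montage = defaultMontage(),
                          samplingRate, events, looking,
                          participantId = "p01", ageGroup = c("younger", "older"),
                          usable = rep(TRUE, 46L), prepandemic = TRUE) {
    ageGroup <- match.arg(ageGroup)
    wl780 <- as.matrix(wl780)
    wl850 <- as.matrix(wl850)
    stopifnot(identical(dim(wl780), dim(wl850)))
    rd <- S4Vectors::DataFrame(channelTable(montage), usable = usable)
    rownames(wl780) <- rownames(wl850) <- as.character(channelTable(montage)$id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = SimpleList(wl780 = wl780, wl850 = wl850),
        rowData = rd)
    metadata(se) <- list(
        participant_id = participantId,
        age_group = ageGroup,
        sampling_rate = samplingRate,
        wavelengths = c(780, 850),
        events = as.data.frame(events),
        looking = as.numeric(looking),
        prepandemic = isTRUE(prepandemic),
        montage = montage)
    new("NirsRecording", se)
}

#' Recording accessors
#'
#' Metadata and intensity accessors for [NirsRecording-class] objects.
#'
#' @param x a `NirsRecording`.
#' @param value replacement value.
#' @param wavelength `"780"` or `"850"`.
#' @name NirsRecording-accessors
NULL

#' @describeIn NirsRecording-accessors participant identifier.
#' @export
setMethod("participantId", "NirsRecording", function(x) metadata(x)$participant_id)

#' @describeIn NirsRecording-accessors age group (`"younger"`/`"older"`).
#' @export
setMethod("ageGroup", "NirsRecording", function(x) metadata(x)$age_group)

#' @describeIn NirsRecording-accessors sampling rate in Hz.
#' @export
setMethod("samplingRate", "NirsRecording", function(x) metadata(x)$sampling_rate)

#' @describeIn NirsRecording-accessors the event schedule.
#' @export
setMethod("events", "NirsRecording", function(x) metadata(x)$events)

#' @describeIn NirsRecording-accessors per-trial looking proportions.
#' @export
setMethod("looking", "NirsRecording", function(x) metadata(x)$looking)

#' @describeIn NirsRecording-accessors logical channel-usability flags.
#' @export
setMethod("usableChannels", "NirsRecording", function(x)
    SummarizedExperiment::rowData(x)$usable)

#' @describeIn NirsRecording-accessors set the usability flags.
#' @export
setMethod("usableChannels<-", "NirsRecording", function(x, value) {
    SummarizedExperiment::rowData(x)$usable <- value
    x
})

#' @describeIn NirsRecording-accessors intensity matrix at one wavelength.
#' @export
setMethod("intensity", "NirsRecording", function(x, wavelength = c("780", "850")) {
    wavelength <- match.arg(as.character(wavelength), c("780", "850"))
    SummarizedExperiment::assay(x, paste0("wl", wavelength))
})

#' @describeIn NirsRecording-accessors the montage.
#' @export
setMethod("montage", "NirsRecording", function(x) metadata(x)$montage)

#' Sample times of a recording
#' @param x a [NirsRecording-class].
#' @return numeric vector of sample times in seconds (0-based).
#' @export
recordingTimes <- function(x) {
    (seq_len(ncol(x)) - 1L) / samplingRate(x)
}

setMethod("show", "NirsRecording", function(object) {
    ev <- events(object)
    cat("NirsRecording", participantId(object),
        sprintf("(%s group%s)", ageGroup(object),
                if (isTRUE(metadata(object)$prepandemic)) ", pre-pandemic" else ""), "\n")
    cat(sprintf("  %d channels x %d samples @ %g Hz (%.0f s)\n", nrow(object),
        ncol(object), samplingRate(object), ncol(object) / samplingRate(object)))
    cat(sprintf("  %d stimulation trials (%d bimodal, %d alternating), %d usable channels\n",
        sum(ev$condition %in% .CONDITIONS), sum(ev$condition == "bimodal"),
        sum(ev$condition == "alternating"), sum(usableChannels(object))))
})
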