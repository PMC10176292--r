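#' Write a recording in the tabular dialect
#'
#' One directory per recording: a long-format `intensity.tsv`
#' (`channel`, `wavelength`, `time_s`, `value`) plus a `meta.json` sidecar
#' holding participant metadata, events, looking proportions, usability flags
#' and the montage.  The format is plain text, diffable, and round-trips to
#' floating-point precision.
#'
#' @param rec a [NirsRecording-class].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    t <- recordingTimes(rec)
    long <- data.table::rbindlist(lapply(c("780", "850"), function(wl) {
        I <- intensity(rec, wl)
        data.table::data.table(
            channel = rep(1:46, each = length(t)),
            wavelength = as.integer(wl),
            time_s = rep(t, times = 46L),
            value = as.vector(t(I)))
    }))
    data.table::fwrite(long, file.path(path, "intensity.tsv"), sep = "\t")
    mont <- montage(rec)
    meta <- list(
        participant_id = participantId(rec),
        age_group = ageGroup(rec),
        sampling_rate = samplingRate(rec),
        wavelengths = c(780, 850),
        prepandemic = isTRUE(metadata(rec)$prepandemic),
        events = events(rec),
        looking = looking(rec),
        channel_usable = as.logical(usableChannels(rec)),
        montage = list(channels = channelTable(mont), adjacency = mont@adjacency))
    jsonlite::write_json(meta, file.path(path, "meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' Read a recording
#'
#' @param path recording directory written by [writeRecording()].
#' @param dialect only the tabular dialect is supported; `"snirf"` names the
#'   HDF5-based interchange container, which this package does not read.
#' @return a validated [NirsRecording-class].
#' @export
readRecording <- function(path, dialect = c("tabular", "snirf")) {
    dialect <- match.arg(dialect)
    if (dialect == "snirf")
        stop("the snirf (HDF5) dialect is not supported; use the tabular dialect")
    fint <- file.path(path, "intensity.tsv")
    fmeta <- file.path(path, "meta.json")
    if (!file.exists(fint) || !file.exists(fmeta))
        stop("recording directory must contain intensity.tsv and meta.json")
    long <- as.data.frame(data.table::fread(fint))
    need <- c("channel", "wavelength", "time_s", "value")
    if (!all(need %in% names(long)))
        stop("intensity schema error: need columns ", paste(need, collapse = ", "))
    if (!identical(sort(unique(long$channel)), 1:46))
        stop("intensity schema error in field 'channel': expected channels 1..46")
    if (!identical(sort(unique(long$wavelength)), c(780L, 850L)))
        stop("intensity schema error in field 'wavelength': expected 780 and 850")
    mats <- lapply(c(780L, 850L), function(wl) {
        sub <- long[long$wavelength == wl, , drop = FALSE]
        m <- matrix(NA_real_, 46L, nrow(sub) / 46L)
        for (ch in 1:46) {
            s <- sub[sub$channel == ch, , drop = FALSE]
            if (is.unsorted(s$time_s, strictly = TRUE))
                stop("intensity format error: time must be strictly increasing")
            m[ch, ] <- s$value
        }
        m
    })
    meta <- jsonlite::read_json(fmeta, simplifyVector = TRUE)
    adjacency <- lapply(meta$montage$adjacency, as.integer)
    mont <- new("NirsMontage",
        channels = as.data.frame(meta$montage$channels), adjacency = adjacency)
    rec <- NirsRecording(mats[[1L]], mats[[2L]], montage = mont,
        samplingRate = meta$sampling_rate,
        events = as.data.frame(meta$events), looking = meta$looking,
        participantId = meta$participant_id, ageGroup = meta$age_group,
        usable = meta$channel_usable, prepandemic = meta$prepandemic)
    rec
}

#' Summarise decoding results as a table
#'
#' @param decodings list of [NirsDecoding-class] objects.
#' @return `data.frame`, one row per analysis.
#' @export
decodingSummary <- function(decodings) {
    if (!length(decodings))
        return(data.frame(age_group = character(), chromophore = character(),
            window = character(), subset = character(), accuracy = numeric(),
            accuracy_both_correct = numeric(), n_folds = integer(),
            p = numeric(), n_perm = integer(), informative = character()))
    do.call(rbind, lapply(decodings, function(d) data.frame(
        age_group = d@ageGroup, chromophore = d@chromophore, window = d@window,
        subset = d@subset, accuracy = d@accuracy,
        accuracy_both_correct = d@accuracyBothCorrect, n_folds = d@nFolds,
        p = d@permP, n_perm = d@nPerm,
        informative = paste(d@informative, collapse = ","))))
}

# Tiny deterministic polynomial hash of a JSON-serialised object, for
# manifests.
.configHash <- function(x) {
    s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
    h <- 0
    for (b in utf8ToInt(as.character(s)))
        h <- (h * 131 + b) %% 1000000007
    sprintf("%09d", h)
}

.table2Layout <- function(stats) {
    if (!nrow(stats))
        return(data.frame(Chrom = character(), H = character(), ROI = character(),
            CH = integer(), TW = character(), F = numeric(), df = integer(),
            df_error = integer(), p = numeric(), eta_sq_p = numeric(),
            posthoc_p = numeric(), direction = character(), label = character(),
            fdr_significant = logical(), age_group = character(), n = integer()))
    data.frame(
        Chrom = stats$chromophore,
        H = ifelse(stats$hemisphere == "left", "L", "R"),
        ROI = c(inferior_frontal = "IF", superior_temporal = "ST",
                other = "-")[stats$region],
        CH = stats$channel,
        TW = c(W1 = "5-10s", W2 = "10-15s")[stats$window],
        F = stats$F, df = stats$df1, df_error = stats$df2, p = stats$p,
        eta_sq_p = stats$eta_p2, posthoc_p = stats$posthoc_p,
        direction = stats$direction, label = stats$label,
        fdr_significant = stats$fdr_significant,
        age_group = stats$age_group, n = stats$n)
}

.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write result tables and a run manifest
#'
#' Emits tab-separated tables ('.' decimal separator): channel statistics in
#' the published result-table layout (`channel_stats.tsv`), the decoding
#' summary (`decoding.tsv`), the power table (`power.tsv`), the QC/attrition
#' report (`qc.tsv`) and the window means (`window_means.tsv`), plus a
#' machine-readable `manifest.json` (config echo and hash, seed, package
#' version).  Empty tables produce header-only files.  Re-running with the
#' same inputs produces byte-identical files (no timestamps).
#'
#' @param results named list; recognised components: `channelStats`,
#'   `decoding` (a [decodingSummary()] table or list of decodings), `power`,
#'   `qc`, `windowMeans`, `config`, `seed`.
#' @param dir output directory (created).
#' @return character vector of file paths, invisibly.
#' @export
writeResults <- function(results, dir) {
    ok <- tryCatch({
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        dir.exists(dir)
    }, error = function(e) FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
    files <- character()
    if (!is.null(results$channelStats)) {
        f <- file.path(dir, "channel_stats.tsv")
        .writeTSV(.table2Layout(results$channelStats), f)
        files <- c(files, f)
    }
    if (!is.null(results$decoding)) {
        dec <- results$decoding
        if (!is.data.frame(dec)) dec <- decodingSummary(dec)
        f <- file.path(dir, "decoding.tsv")
        .writeTSV(dec, f)
        files <- c(files, f)
    }
    for (nm in c("power", "qc", "windowMeans")) {
        if (is.null(results[[nm]])) next
        f <- file.path(dir, paste0(c(power = "power", qc = "qc",
            windowMeans = "window_means")[[nm]], ".tsv"))
        .writeTSV(results[[nm]], f)
        files <- c(files, f)
    }
    manifest <- list(
        package = "infnirs",
        version = as.character(utils::packageVersion("infnirs")),
        seed = results$seed,
        config = results$config,
        config_hash = .configHash(results$config),
        files = basename(files))
    fm <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, fm, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(c(files, fm))
}
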