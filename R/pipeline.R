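#' Run configuration for the full pipeline
#'
#' @param simulation a [simulationConfig()] (simulation-backed runs), or
#'   `NULL` when `recordings` is given.
#' @param recordings a list of [NirsRecording-class] objects or a directory
#'   of recording subdirectories in the tabular dialect.
#' @param params a [preprocessParams()].
#' @param analyses character subset of `c("univariate", "decoding", "power")`.
#' @param decoding list of decoding options: `chromophores`, `windows`,
#'   `subsets`, `nPerm`.
#' @param prepandemicOnly re-run the decoding analyses on the pre-pandemic
#'   participants only.
#' @param seed mandatory integer seed for the analysis stages.
#' @param outDir output directory.
#' @return a validated `infnirs_run_config` list.
#' @export
runConfig <- function(simulation = NULL, recordings = NULL,
                      params = preprocessParams(),
                      analyses = c("univariate", "decoding", "power"),
                      decoding = list(), prepandemicOnly = FALSE,
                      seed, outDir) {
    if (missing(seed)) stop("a seed is mandatory")
    if (missing(outDir)) stop("an output directory is required")
    if (is.null(simulation) && is.null(recordings))
        stop("provide either a simulation config or recordings")
    decoding <- utils::modifyList(list(chromophores = "HbO", windows = "W2",
        subsets = "all", nPerm = 200L), decoding)
    cfg <- list(simulation = simulation, recordings = recordings,
        params = params, analyses = analyses, decoding = decoding,
        prepandemicOnly = isTRUE(prepandemicOnly), seed = as.integer(seed),
        outDir = outDir)
    class(cfg) <- "infnirs_run_config"
    cfg
}

#' Execute the configured stages and write the result bundle
#'
#' Simulate (or read) the cohort, preprocess with the inclusion rules, then
#' run the enabled analyses: channel-by-channel planned contrasts per age
#' group, decoding per age group and configured chromophore/window/subset
#' combination, and the achieved-power table.  Everything is written via
#' [writeResults()]; identical config and seed produce a byte-identical
#' bundle.
#'
#' @param config a [runConfig()].
#' @return the result list, invisibly (components as in [writeResults()]).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "infnirs_run_config"))
    recs <- if (!is.null(config$simulation)) {
        simulateCohort(config$simulation)$recordings
    } else if (is.character(config$recordings)) {
        dirs <- list.dirs(config$recordings, recursive = FALSE)
        lapply(dirs, readRecording)
    } else config$recordings

    pp <- preprocessCohort(recs, config$params)
    wm <- pp$windowMeans
    groups <- unique(wm$age_group)
    results <- list(qc = pp$qc, windowMeans = wm,
        config = list(params = unclass(config$params),
            analyses = config$analyses, decoding = config$decoding,
            prepandemicOnly = config$prepandemicOnly,
            simulation = if (!is.null(config$simulation))
                unclass(config$simulation)),
        seed = config$seed)

    if ("univariate" %in% config$analyses && nrow(wm)) {
        results$channelStats <- do.call(rbind, lapply(groups, function(g)
            channelStats(wm, ageGroup = g)))
    }
    if ("decoding" %in% config$analyses && nrow(wm)) {
        dec <- list()
        for (g in groups) for (chrom in config$decoding$chromophores)
            for (w in config$decoding$windows)
                for (ss in config$decoding$subsets) {
                    d <- tryCatch(decodeConditions(wm, chromophore = chrom,
                            window = w, subset = ss, ageGroup = g,
                            prepandemicOnly = config$prepandemicOnly,
                            nPerm = config$decoding$nPerm, seed = config$seed),
                        error = function(e) {
                            message(sprintf("decoding %s/%s/%s/%s skipped: %s",
                                g, chrom, w, ss, conditionMessage(e)))
                            NULL
                        })
                    if (!is.null(d)) dec[[length(dec) + 1L]] <- d
                }
        results$decoding <- decodingSummary(dec)
    }
    if ("power" %in% config$analyses) {
        nInc <- table(pp$qc$age_group[pp$qc$included])
        rows <- lapply(names(nInc), function(g) data.frame(
            analysis = g, n = as.integer(nInc[[g]]),
            power = rmWithinPower(0.25, max(2L, as.integer(nInc[[g]])),
                                  m = 6, rho = 0.6, eps = 0.75)))
        results$power <- do.call(rbind, rows)
    }
    writeResults(results, config$outDir)
    invisible(results)
}
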