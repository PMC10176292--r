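#' Default 46-channel infant montage
#'
#' Builds the montage used throughout the package: 46 source-detector channels
#' at 2 cm separation covering frontal to temporoparietal cortex bilaterally.
#' Channels 1-23 lie over the left hemisphere and 24-46 over the right.  The
#' region labels are a reconstruction of the published array diagram: the
#' inferior frontal region comprises channels 3 and 4 (left) and 24 and 26
#' (right); the superior temporal region comprises channels 5 and 15 (left)
#' and 27, 28, 29 and 31 (right).  All other channels are tagged `"other"`.
#' Adjacency links consecutive channel ids within a hemisphere - a simplified
#' stand-in for the true optical-array geometry, which the package does not
#' need beyond symmetry.
#'
#' @param separation_cm source-detector separation in centimetres (default 2).
#' @return A [NirsMontage-class] object.
#' @examples
#' m <- defaultMontage()
#' regionChannels(m, "inferior_frontal")
#' @export
defaultMontage <- function(separation_cm = 2.0) {
    id <- 1:46
    hemisphere <- ifelse(id <= 23L, "left", "right")
    region <- rep("other", 46L)
    region[c(3L, 4L, 24L, 26L)] <- "inferior_frontal"
    region[c(5L, 15L, 27L, 28L, 29L, 31L)] <- "superior_temporal"
    within_id <- ifelse(id <= 23L, id, id - 23L)
    channels <- data.frame(
        id = id,
        source_id = (within_id - 1L) %/% 2L + 1L + ifelse(id <= 23L, 0L, 12L),
        detector_id = within_id %/% 2L + 1L + ifelse(id <= 23L, 0L, 12L),
        hemisphere = hemisphere,
        region = region,
        separation_cm = separation_cm,
        stringsAsFactors = FALSE)
    adjacency <- lapply(id, function(i) {
        nb <- c(i - 1L, i + 1L)
        nb[nb >= 1L & nb <= 46L & (nb <= 23L) == (i <= 23L)]
    })
    names(adjacency) <- as.character(id)
    new("NirsMontage", channels = channels, adjacency = adjacency)
}

#' @describeIn NirsMontage-accessors the channel annotation `data.frame`.
#' @export
setMethod("channelTable", "NirsMontage", function(x) x@channels)

#' Montage accessors
#'
#' @param x a [NirsMontage-class].
#' @param hemisphere `"left"` or `"right"`.
#' @param region one of `"inferior_frontal"`, `"superior_temporal"`, `"other"`.
#' @param id a channel id.
#' @name NirsMontage-accessors
NULL

#' @describeIn NirsMontage-accessors integer ids of the channels over one
#'   hemisphere.
#' @export
setMethod("hemisphereChannels", "NirsMontage", function(x, hemisphere) {
    hemisphere <- match.arg(hemisphere, c("left", "right"))
    x@channels$id[x@channels$hemisphere == hemisphere]
})

#' @describeIn NirsMontage-accessors integer ids of the channels in a region.
#' @export
setMethod("regionChannels", "NirsMontage", function(x, region) {
    region <- match.arg(region, .REGIONS)
    x@channels$id[x@channels$region == region]
})

#' @describeIn NirsMontage-accessors neighbouring channel ids.
#' @export
setMethod("neighborChannels", "NirsMontage", function(x, id) {
    x@adjacency[[as.character(id)]]
})

setMethod("show", "NirsMontage", function(object) {
    ch <- object@channels
    cat("NirsMontage:", nrow(ch), "channels,",
        sum(ch$hemisphere == "left"), "left /", sum(ch$hemisphere == "right"), "right\n")
    cat("  inferior frontal: ", paste(ch$id[ch$region == "inferior_frontal"], collapse = ", "), "\n")
    cat("  superior temporal:", paste(ch$id[ch$region == "superior_temporal"], collapse = ", "), "\n")
    cat("  separation:", unique(ch$separation_cm), "cm\n")
})
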