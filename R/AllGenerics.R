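#' @rdname NirsRecording-accessors
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))

#' @rdname NirsRecording-accessors
#' @export
setGeneric("ageGroup", function(x) standardGeneric("ageGroup"))

#' @rdname NirsRecording-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname NirsRecording-accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname NirsRecording-accessors
#' @export
setGeneric("looking", function(x) standardGeneric("looking"))

#' @rdname NirsRecording-accessors
#' @export
setGeneric("usableChannels", function(x) standardGeneric("usableChannels"))

#' @rdname NirsRecording-accessors
#' @export
setGeneric("usableChannels<-", function(x, value) standardGeneric("usableChannels<-"))

#' @rdname NirsRecording-accessors
#' @export
setGeneric("intensity", function(x, wavelength = c("780", "850"))
    standardGeneric("intensity"))

#' @rdname NirsRecording-accessors
#' @export
setGeneric("montage", function(x) standardGeneric("montage"))

#' @rdname NirsMontage-accessors
#' @export
setGeneric("channelTable", function(x) standardGeneric("channelTable"))

#' @rdname NirsMontage-accessors
#' @export
setGeneric("hemisphereChannels", function(x, hemisphere) standardGeneric("hemisphereChannels"))

#' @rdname NirsMontage-accessors
#' @export
setGeneric("regionChannels", function(x, region) standardGeneric("regionChannels"))

#' @rdname NirsMontage-accessors
#' @export
setGeneric("neighborChannels", function(x, id) standardGeneric("neighborChannels"))
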