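#' @name accessors
#' @title Accessors for EEG data objects
#' @description Slot accessors for [EEGClip-class], [EEGSegment-class] and
#'   [ScalogramStack-class] objects. Use these rather than `@`.
#' @param object an EEGClip, EEGSegment or ScalogramStack.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("clipId", function(object) standardGeneric("clipId"))
#' @rdname accessors
#' @export
setGeneric("clipLabel", function(object) standardGeneric("clipLabel"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("clipData", function(object) standardGeneric("clipData"))
#' @rdname accessors
#' @export
setGeneric("segmentIndex", function(object) standardGeneric("segmentIndex"))
#' @rdname accessors
#' @export
setGeneric("stackImages", function(object) standardGeneric("stackImages"))
#' @rdname accessors
#' @export
setGeneric("stackFreqs", function(object) standardGeneric("stackFreqs"))

for (cls in c("EEGClip", "EEGSegment", "ScalogramStack")) {
  setMethod("subjectId", cls, function(object) object@subjectId)
  setMethod("clipId", cls, function(object) object@clipId)
  setMethod("clipLabel", cls, function(object) object@label)
  setMethod("channelNames", cls, function(object) object@channelNames)
}

setMethod("samplingRate", "EEGClip", function(object) object@fs)
setMethod("samplingRate", "EEGSegment", function(object) object@fs)
setMethod("nChannels", "EEGClip", function(object) nrow(object@data))
setMethod("nChannels", "EEGSegment", function(object) nrow(object@data))
setMethod("nChannels", "ScalogramStack", function(object) length(object@images))
setMethod("channelNames", "ScalogramStack", function(object) object@channelNames)
setMethod("clipData", "EEGClip", function(object) object@data)
setMethod("clipData", "EEGSegment", function(object) object@data)
setMethod("segmentIndex", "EEGSegment", function(object) object@segmentIndex)
setMethod("segmentIndex", "ScalogramStack", function(object) object@segmentIndex)
setMethod("stackImages", "ScalogramStack", function(object) object@images)
setMethod("stackFreqs", "ScalogramStack", function(object) object@freqs)
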