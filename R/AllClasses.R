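#' EEGClip: one labeled multichannel EEG clip
#'
#' Container for a single EEG clip: an N x D matrix of amplitudes in
#' microvolts (one row per channel), its sampling rate, a clip-level class
#' label and provenance identifiers. Clips are the unit of labeling; 10-s
#' segments cut from a clip inherit its label.
#'
#' @slot subjectId character(1), subject identifier (the unit held out by
#'   leave-one-subject-out cross-validation).
#' @slot clipId character(1), unique clip identifier.
#' @slot label one of `"preictal"`, `"interictal"`, `"unlabeled"`.
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot channelNames character(N).
#' @slot data numeric N x D matrix of amplitudes (microvolts).
#'
#' @exportClass EEGClip
setClass("EEGClip",
  representation(
    subjectId = "character",
    clipId = "character",
    label = "character",
    fs = "numeric",
    channelNames = "character",
    data = "matrix"
  )
)

setValidity("EEGClip", function(object) {
  msg <- character()
  if (length(object@label) != 1L ||
      !object@label %in% c("preictal", "interictal", "unlabeled"))
    msg <- c(msg, "label must be one of 'preictal', 'interictal', 'unlabeled'")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@data) < 1L)
    msg <- c(msg, "clip must have at least one channel")
  if (length(object@channelNames) != nrow(object@data))
    msg <- c(msg, "channelNames length must equal the number of channels")
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGClip
#'
#' @param data numeric N x D matrix of amplitudes in microvolts, one row per
#'   channel.
#' @param fs sampling rate in Hz.
#' @param label clip-level class label: `"preictal"`, `"interictal"` or
#'   `"unlabeled"`.
#' @param subjectId,clipId identifiers.
#' @param channelNames optional character vector of channel names; defaults
#'   to `"ch01"`, `"ch02"`, ...
#' @return an [EEGClip-class] object.
#' @export
eegClip <- function(data, fs, label = "unlabeled", subjectId = "S01",
                    clipId = "clip01", channelNames = NULL) {
  if (is.null(channelNames))
    channelNames <- sprintf("ch%02d", seq_len(nrow(data)))
  new("EEGClip", subjectId = as.character(subjectId),
      clipId = as.character(clipId), label = label, fs = as.numeric(fs),
      channelNames = channelNames, data = data)
}

#' EEGSegment: one 10-s segment cut from a clip
#'
#' @slot subjectId,clipId,label inherited from the parent clip.
#' @slot segmentIndex integer(1), 0-based index within the parent clip.
#' @slot fs numeric(1), Hz.
#' @slot data numeric N x d matrix, d = segment length in samples.
#'
#' @exportClass EEGSegment
setClass("EEGSegment",
  representation(
    subjectId = "character",
    clipId = "character",
    label = "character",
    segmentIndex = "integer",
    fs = "numeric",
    data = "matrix"
  )
)

setValidity("EEGSegment", function(object) {
  msg <- character()
  if (object@segmentIndex < 0L) msg <- c(msg, "segmentIndex must be >= 0")
  if (nrow(object@data) < 1L) msg <- c(msg, "segment must have >= 1 channel")
  if (length(msg)) msg else TRUE
})

#' ScalogramStack: per-channel time-frequency images for one segment
#'
#' One wavelet-power image per EEG channel for a single 10-s segment. The
#' frequency axis is stored as the row center frequencies in descending
#' order (row 1 = highest frequency).
#'
#' @slot subjectId,clipId,label,segmentIndex provenance, inherited from the
#'   segment.
#' @slot channelNames character(N).
#' @slot freqs numeric(H), row center frequencies in Hz, strictly descending.
#' @slot images list of N numeric H x W matrices.
#'
#' @exportClass ScalogramStack
setClass("ScalogramStack",
  representation(
    subjectId = "character",
    clipId = "character",
    label = "character",
    segmentIndex = "integer",
    channelNames = "character",
    freqs = "numeric",
    images = "list"
  )
)

setValidity("ScalogramStack", function(object) {
  msg <- character()
  if (length(object@images) < 1L)
    msg <- c(msg, "stack must contain at least one image")
  dims <- vapply(object@images, dim, integer(2))
  if (length(object@images) > 1L && any(dims != dims[, 1]))
    msg <- c(msg, "all images must share the same shape")
  if (dims[1, 1] != length(object@freqs))
    msg <- c(msg, "freqs length must equal the image height")
  if (length(object@freqs) > 1L && any(diff(object@freqs) >= 0))
    msg <- c(msg, "freqs must be strictly descending")
  if (length(object@channelNames) != length(object@images))
    msg <- c(msg, "one channel name per image required")
  if (length(msg)) msg else TRUE
})

#' MetricsReport: classification metrics at a stated threshold
#'
#' Sensitivity, specificity and accuracy are computed from the confusion
#' counts at `threshold`; `fprPerHour` is false positives per hour of
#' interictal recording evaluated; `auc` is threshold-free. Metrics whose
#' defining class is absent from the evaluation set are `NA` (undefined),
#' never zero.
#'
#' @slot sens,spec,acc numeric(1) in [0, 1] or NA.
#' @slot fprPerHour numeric(1) >= 0 or NA.
#' @slot auc numeric(1) in [0, 1] or NA.
#' @slot threshold numeric(1), the decision threshold used.
#' @slot counts numeric(4), named TP/FN/TN/FP confusion counts.
#'
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    sens = "numeric",
    spec = "numeric",
    acc = "numeric",
    fprPerHour = "numeric",
    auc = "numeric",
    threshold = "numeric",
    counts = "numeric"
  )
)

setValidity("MetricsReport", function(object) {
  msg <- character()
  for (nm in c("sens", "spec", "acc", "auc")) {
    v <- slot(object, nm)
    if (!is.na(v) && (v < 0 || v > 1))
      msg <- c(msg, sprintf("%s must be in [0, 1] or NA", nm))
  }
  if (!is.na(object@fprPerHour) && object@fprPerHour < 0)
    msg <- c(msg, "fprPerHour must be >= 0 or NA")
  if (!identical(sort(names(object@counts)), sort(c("TP", "FN", "TN", "FP"))))
    msg <- c(msg, "counts must be named TP, FN, TN, FP")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EEGClip", function(object) {
  cat(sprintf("EEGClip %s (subject %s, %s)\n", object@clipId,
              object@subjectId, object@label))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
})

setMethod("show", "EEGSegment", function(object) {
  cat(sprintf("EEGSegment %s[%d] (subject %s, %s): %d x %d @ %g Hz\n",
              object@clipId, object@segmentIndex, object@subjectId,
              object@label, nrow(object@data), ncol(object@data), object@fs))
})

setMethod("show", "ScalogramStack", function(object) {
  d <- dim(object@images[[1]])
  cat(sprintf("ScalogramStack %s[%d] (%s): %d images of %d x %d, %.2f-%.2f Hz\n",
              object@clipId, object@segmentIndex, object@label,
              length(object@images), d[1], d[2],
              min(object@freqs), max(object@freqs)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0("MetricsReport @ threshold %.2f\n",
                     "  SENS %.4f  SPEC %.4f  ACC %.4f  FPR/h %.4f  AUC %.4f\n"),
              object@threshold, object@sens, object@spec, object@acc,
              object@fprPerHour, object@auc))
  cat(sprintf("  counts: TP=%d FN=%d TN=%d FP=%d\n",
              object@counts["TP"], object@counts["FN"],
              object@counts["TN"], object@counts["FP"]))
})
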