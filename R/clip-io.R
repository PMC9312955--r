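#' Write an EEG clip as a competition-style container
#'
#' Writes the clip as a little-endian MAT v5 container with variables `data`
#' (channels x samples, microvolts, 64-bit floats so amplitudes round-trip
#' bit-exactly), `fs` (scalar Hz) and `channels` (channel names), plus a JSON
#' sidecar `<path>.json` carrying subject id, clip id and label. Containers
#' written here are read back field-for-field by [readCompetitionClip()].
#'
#' @param clip an [EEGClip-class].
#' @param path output path (conventionally `.mat`).
#' @return `path`, invisibly.
#' @export
writeClip <- function(clip, path) {
  validObject(clip)
  if (!dir.exists(dirname(path)))
    stopData("unwritable path (no such directory): ", dirname(path))
  writeMat5(path, list(data = clip@data, fs = clip@fs,
                       channels = clip@channelNames))
  writeJson(list(subject_id = clip@subjectId, clip_id = clip@clipId,
                 label = clip@label, fs = clip@fs,
                 n_channels = nrow(clip@data),
                 duration_s = ncol(clip@data) / clip@fs),
            paste0(path, ".json"))
  invisible(path)
}

inferLabelFromName <- function(name) {
  if (grepl("interictal", name, ignore.case = TRUE)) return("interictal")
  if (grepl("preictal", name, ignore.case = TRUE)) return("preictal")
  NA_character_
}

#' Read a competition-style 10-min EEG clip container
#'
#' Reads a MAT v5 clip container holding a channels x samples `data` array, a
#' scalar `fs` and (optionally) `channels` names. The class label is taken
#' from the JSON sidecar when one exists, otherwise inferred from the file
#' name (which must contain "preictal" or "interictal", the competition
#' convention). Conforming invasive-EEG containers yield 16 x 240,000 clips
#' at 400 Hz.
#'
#' @param path container path.
#' @return an [EEGClip-class].
#' @export
readCompetitionClip <- function(path) {
  if (!file.exists(path)) stopData("no such clip container: ", path)
  vars <- readMat5(path)
  if (is.null(vars$data)) stopData("container missing 'data' array: ", path)
  if (is.null(vars$fs)) stopData("container missing 'fs' field: ", path)
  data <- vars$data
  fs <- as.numeric(vars$fs)[1]
  channels <- if (!is.null(vars$channels)) as.character(vars$channels) else
    sprintf("ch%02d", seq_len(nrow(data)))
  sidecar <- paste0(path, ".json")
  base <- sub("\\.[^.]+$", "", basename(path))
  if (file.exists(sidecar)) {
    meta <- readJson(sidecar)
    label <- meta$label
    subject <- meta$subject_id
    clipId <- meta$clip_id
  } else {
    label <- inferLabelFromName(basename(path))
    if (is.na(label))
      stopData("label not inferable from file name: ", basename(path))
    subject <- sub("[._-]?(pre|inter)ictal.*$", "", base, ignore.case = TRUE)
    if (!nzchar(subject)) subject <- base
    clipId <- base
  }
  eegClip(data, fs, label, subject, clipId, channels)
}
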