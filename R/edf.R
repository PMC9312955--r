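# European Data Format (EDF) reader. EDF is a fixed-width ASCII header
# followed by little-endian 16-bit integer data records; physical values are
# recovered by the per-signal linear digital->physical calibration. Amplitudes
# are converted to microvolts on read (the package-internal unit).

edfField <- function(hdr, from, width) {
  trimws(substr(hdr, from, from + width - 1L))
}

unitToMicrovolt <- function(dim) {
  switch(tolower(dim), "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6, 1)
}

#' Read an EDF recording
#'
#' Reads all ordinary signals of an EDF file into a channels x samples matrix
#' of microvolt amplitudes. Annotation channels ("EDF Annotations") are
#' skipped. All retained channels must share one sampling rate.
#'
#' @param path path to an EDF file.
#' @param maxChannels optional cap on the number of channels kept, in
#'   recording order (e.g. 23 to normalize recordings with surplus
#'   electrodes); `NULL` keeps all.
#' @return a list with elements `data` (N x D matrix, microvolts), `fs` (Hz),
#'   `channelNames`, and `durationS`.
#' @export
readEDF <- function(path, maxChannels = NULL) {
  if (!file.exists(path)) stopData("no such EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, raw(), 256L))
  if (nchar(hdr, type = "bytes") < 256L || edfField(hdr, 1, 8) != "0")
    stopData("not a valid EDF file: ", path)
  nRecords <- as.integer(edfField(hdr, 237, 8))
  recDur <- as.numeric(edfField(hdr, 245, 8))
  ns <- as.integer(edfField(hdr, 253, 4))
  if (is.na(nRecords) || is.na(recDur) || is.na(ns) || ns < 1L)
    stopData("corrupt EDF header: ", path)
  sig <- rawToChar(readBin(con, raw(), 256L * ns))
  fieldBlock <- function(offset, width) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig, offset + (i - 1L) * width + 1L,
                    offset + i * width)), character(1))
  }
  off <- 0L
  labels <- fieldBlock(off, 16L); off <- off + 16L * ns
  off <- off + 80L * ns # transducer
  physDim <- fieldBlock(off, 8L); off <- off + 8L * ns
  physMin <- as.numeric(fieldBlock(off, 8L)); off <- off + 8L * ns
  physMax <- as.numeric(fieldBlock(off, 8L)); off <- off + 8L * ns
  digMin <- as.numeric(fieldBlock(off, 8L)); off <- off + 8L * ns
  digMax <- as.numeric(fieldBlock(off, 8L)); off <- off + 8L * ns
  off <- off + 80L * ns # prefiltering
  spr <- as.integer(fieldBlock(off, 8L)) # samples per record per signal

  keep <- which(labels != "EDF Annotations")
  if (!length(keep)) stopData("EDF file has no signal channels: ", path)
  if (!is.null(maxChannels)) keep <- head(keep, maxChannels)
  if (length(unique(spr[keep])) != 1L)
    stopData("EDF channels have differing sampling rates: ", path)
  fs <- spr[keep[1]] / recDur

  total <- sum(spr)
  raw16 <- readBin(con, integer(), n = nRecords * total, size = 2L,
                   signed = TRUE, endian = "little")
  if (length(raw16) < nRecords * total)
    stopData("EDF data truncated: ", path)
  offs <- c(0L, cumsum(spr))
  data <- matrix(0, length(keep), nRecords * spr[keep[1]])
  recBase <- (seq_len(nRecords) - 1L) * total
  for (kk in seq_along(keep)) {
    i <- keep[kk]
    idx <- as.vector(outer(seq_len(spr[i]) + offs[i], recBase, `+`))
    scale <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    vals <- (raw16[idx] - digMin[i]) * scale + physMin[i]
    data[kk, ] <- vals * unitToMicrovolt(physDim[i])
  }
  list(data = data, fs = fs, channelNames = labels[keep],
       durationS = nRecords * recDur)
}

# Minimal EDF writer (internal; used to synthesize EDF fixtures in tests and
# examples). One-second records, symmetric physical range per channel,
# microvolt units.
writeEDF <- function(path, data, fs, channelNames = NULL) {
  n <- nrow(data)
  if (is.null(channelNames)) channelNames <- sprintf("ch%02d", seq_len(n))
  stopifnot(fs == round(fs), ncol(data) %% fs == 0)
  nRecords <- ncol(data) / fs
  physMax <- pmax(apply(abs(data), 1L, max), 1)
  fw <- function(x, w) formatC(as.character(x), width = -w)
  hdr <- paste0(
    fw("0", 8), fw("synthetic", 80), fw("synthetic recording", 80),
    fw("01.01.20", 8), fw("00.00.00", 8), fw(256L * (n + 1L), 8), fw("", 44),
    fw(nRecords, 8), fw(1, 8), fw(n, 4))
  sig <- paste0(
    paste(fw(channelNames, 16), collapse = ""),
    paste(fw(rep("", n), 80), collapse = ""),
    paste(fw(rep("uV", n), 8), collapse = ""),
    paste(fw(formatC(-physMax, format = "g", digits = 6), 8), collapse = ""),
    paste(fw(formatC(physMax, format = "g", digits = 6), 8), collapse = ""),
    paste(fw(rep(-32768L, n), 8), collapse = ""),
    paste(fw(rep(32767L, n), 8), collapse = ""),
    paste(fw(rep("", n), 80), collapse = ""),
    paste(fw(rep(fs, n), 8), collapse = ""),
    paste(fw(rep("", n), 32), collapse = ""))
  dig <- matrix(0L, n, ncol(data))
  for (i in seq_len(n)) {
    pm <- as.numeric(formatC(physMax[i], format = "g", digits = 6))
    dig[i, ] <- as.integer(round((data[i, ] + pm) / (2 * pm) * 65535 - 32768))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  # interleave: per record, per signal, fs samples
  out <- integer(length(dig))
  pos <- 1L
  for (r in seq_len(nRecords)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(n)) {
      out[pos:(pos + fs - 1L)] <- dig[i, cols]
      pos <- pos + fs
    }
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

#' Cut labeled 10-min clips from an EDF recording
#'
#' Cuts non-overlapping fixed-length clips from labeled time intervals of an
#' EDF recording. The label intervals follow the usual seizure-prediction
#' conventions: preictal intervals cover the hour before a seizure onset
#' minus a five-minute offset; interictal intervals lie more than four hours
#' from any seizure. This function takes the intervals as given and does not
#' re-derive them from annotations. Partial trailing clips are dropped, so
#' the total cut duration per interval is `floor(length / clipLenS) * clipLenS`.
#'
#' @param path EDF file path.
#' @param labelSpec data.frame with columns `start_s`, `end_s`, `label`
#'   (record time in seconds; label `"preictal"` or `"interictal"`).
#' @param subjectId subject identifier attached to the clips; defaults to the
#'   file base name.
#' @param clipLenS clip length in seconds (default 600 = 10 min).
#' @param maxChannels see [readEDF()].
#' @return list of [EEGClip-class] objects.
#' @export
readEDFClips <- function(path, labelSpec, subjectId = NULL, clipLenS = 600,
                         maxChannels = NULL) {
  if (is.null(subjectId)) subjectId <- sub("\\.edf$", "", basename(path),
                                           ignore.case = TRUE)
  if (nrow(labelSpec) == 0L) return(list())
  if (!all(c("start_s", "end_s", "label") %in% names(labelSpec)))
    stopConfig("labelSpec needs columns start_s, end_s, label")
  if (!all(labelSpec$label %in% c("preictal", "interictal")))
    stopConfig("labelSpec labels must be 'preictal' or 'interictal'")
  # contradictory overlap check
  if (nrow(labelSpec) > 1L) {
    for (i in seq_len(nrow(labelSpec) - 1L)) {
      for (j in (i + 1L):nrow(labelSpec)) {
        if (labelSpec$start_s[i] < labelSpec$end_s[j] &&
            labelSpec$start_s[j] < labelSpec$end_s[i] &&
            labelSpec$label[i] != labelSpec$label[j])
          stopData("overlapping intervals with contradictory labels")
      }
    }
  }
  rec <- readEDF(path, maxChannels = maxChannels)
  if (any(labelSpec$end_s > rec$durationS + 1e-9))
    stopData("label interval exceeds record length")
  clips <- list()
  for (i in seq_len(nrow(labelSpec))) {
    nClips <- floor((labelSpec$end_s[i] - labelSpec$start_s[i]) / clipLenS)
    for (c0 in seq_len(nClips)) {
      t0 <- labelSpec$start_s[i] + (c0 - 1) * clipLenS
      s0 <- round(t0 * rec$fs)
      cols <- (s0 + 1L):(s0 + clipLenS * rec$fs)
      clips[[length(clips) + 1L]] <- eegClip(
        rec$data[, cols, drop = FALSE], rec$fs, labelSpec$label[i],
        subjectId,
        sprintf("%s_%s_%02d_%02d", subjectId,
                substr(labelSpec$label[i], 1, 3), i, c0),
        rec$channelNames)
    }
  }
  clips
}
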