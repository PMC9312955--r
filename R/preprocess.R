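#' ScalogramConfig: scalogram construction parameters
#'
#' Controls the wavelet scale grid and the image pipeline applied to each
#' 10-s EEG segment channel: wavelet power on `nScales` log-spaced center
#' frequencies in `[fMin, fMax]`, then (in this order) optional `log1p`
#' compression, optional resize to `resizeTo = (H, W)` (area-weighted
#' averaging when downsampling, bilinear interpolation when upsampling),
#' optional per-image z-normalization.
#'
#' @slot nScales number of scales h (image height before resize), >= 2.
#' @slot fMin,fMax frequency range in Hz; `fMax` must not exceed the Nyquist
#'   frequency of the signals the config is applied to.
#' @slot omega0 Morlet shape parameter (dimensionless; default 6).
#' @slot logPower logical, apply `log1p` to the power image.
#' @slot resizeTo integer(2) target (H, W), or integer(0) for no resize.
#' @slot normalize logical, per-image z-score.
#'
#' @exportClass ScalogramConfig
setClass("ScalogramConfig",
  representation(
    nScales = "integer", fMin = "numeric", fMax = "numeric",
    omega0 = "numeric", logPower = "logical", resizeTo = "integer",
    normalize = "logical"
  )
)

setValidity("ScalogramConfig", function(object) {
  msg <- character()
  if (object@nScales < 2L) msg <- c(msg, "nScales must be >= 2")
  if (!(object@fMin > 0 && object@fMin < object@fMax))
    msg <- c(msg, "need 0 < fMin < fMax")
  if (object@omega0 <= 0) msg <- c(msg, "omega0 must be > 0")
  if (!length(object@resizeTo) %in% c(0L, 2L) ||
      (length(object@resizeTo) == 2L && any(object@resizeTo < 2L)))
    msg <- c(msg, "resizeTo must be empty or two integers >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct a ScalogramConfig
#'
#' The default grid is 100 log-spaced center frequencies on [0.5, 50] Hz
#' (clinical EEG bands); the default modeling pipeline is log1p power,
#' resize to 64 x 256 and per-image z-scoring. Pass
#' `resizeTo = NULL` to keep the native h x d image (e.g. 100 x 4000 for a
#' 10-s segment at 400 Hz).
#'
#' @param nScales,fMin,fMax,omega0,logPower,resizeTo,normalize see
#'   [ScalogramConfig-class].
#' @return a validated [ScalogramConfig-class].
#' @export
scalogramConfig <- function(nScales = 100, fMin = 0.5, fMax = 50, omega0 = 6,
                            logPower = TRUE, resizeTo = c(64, 256),
                            normalize = TRUE) {
  tryCatch(
    new("ScalogramConfig", nScales = as.integer(nScales),
        fMin = as.numeric(fMin), fMax = as.numeric(fMax),
        omega0 = as.numeric(omega0), logPower = isTRUE(logPower),
        resizeTo = as.integer(resizeTo %||% integer(0)),
        normalize = isTRUE(normalize)),
    error = function(e) stopConfig(conditionMessage(e)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "ScalogramConfig", function(object) {
  rs <- if (length(object@resizeTo)) sprintf("%dx%d", object@resizeTo[1],
                                             object@resizeTo[2]) else "none"
  cat(sprintf(paste0("ScalogramConfig: %d scales on [%g, %g] Hz (Morlet w0=%g)",
                     "\n  log1p=%s resize=%s z-normalize=%s\n"),
              object@nScales, object@fMin, object@fMax, object@omega0,
              object@logPower, rs, object@normalize))
})

# Center frequencies of the scale grid, descending (row 1 = highest).
scalogramFreqs <- function(cfg, nOut = cfg@nScales) {
  exp(seq(log(cfg@fMax), log(cfg@fMin), length.out = nOut))
}

# Resampling weights for one axis, as a (nOut x nIn) row-stochastic matrix.
# Downsampling uses area-weighted averaging (each output cell is the mean of
# the input cells it covers, partial cells weighted by overlap), which
# integrates -- rather than point-samples -- transient energy; upsampling
# uses bilinear interpolation between cell centers.
resampleWeights <- function(nOut, nIn) {
  W <- matrix(0, nOut, nIn)
  if (nOut <= nIn) {
    step <- nIn / nOut
    for (i in seq_len(nOut)) {
      a <- (i - 1) * step
      b <- i * step
      j0 <- floor(a) + 1L
      j1 <- ceiling(b)
      for (j in j0:min(j1, nIn)) {
        ov <- min(b, j) - max(a, j - 1)
        if (ov > 0) W[i, j] <- ov
      }
    }
  } else {
    # output cell centers mapped onto input cell centers
    for (i in seq_len(nOut)) {
      c0 <- (i - 0.5) * nIn / nOut + 0.5
      j <- floor(c0)
      fr <- c0 - j
      if (j < 1) { W[i, 1] <- 1 }
      else if (j >= nIn) { W[i, nIn] <- 1 }
      else { W[i, j] <- 1 - fr; W[i, j + 1] <- fr }
    }
  }
  W / rowSums(W)
}

# Resize a matrix to H x W by separable area-average / bilinear resampling.
# A weighted average with non-negative weights, so non-negative images stay
# non-negative. The two weight matrices make the whole resize two matrix
# products.
resizeMatrix <- function(img, H, W) {
  resampleWeights(H, nrow(img)) %*% img %*% t(resampleWeights(W, ncol(img)))
}

#' Split an EEG clip into non-overlapping segments
#'
#' Cuts a clip into `floor(duration / segLenS)` contiguous, non-overlapping
#' segments of `segLenS` seconds (default 10 s, giving 60 segments per 10-min
#' clip: d = 2560 samples per channel at 256 Hz, 4000 at 400 Hz). The
#' trailing remainder is dropped. Segments inherit the clip label.
#'
#' @param clip an [EEGClip-class].
#' @param segLenS segment duration in seconds.
#' @return ordered list of [EEGSegment-class], `segmentIndex` 0-based.
#' @export
segmentClip <- function(clip, segLenS = 10) {
  d <- segLenS * clip@fs
  if (abs(d - round(d)) > 1e-9)
    stopConfig("segLenS * fs must be an integer sample count")
  d <- as.integer(round(d))
  nSeg <- ncol(clip@data) %/% d
  if (nSeg < 1L)
    stopData("clip ", clip@clipId, " is shorter than one segment")
  lapply(seq_len(nSeg) - 1L, function(i) {
    new("EEGSegment", subjectId = clip@subjectId, clipId = clip@clipId,
        label = clip@label, segmentIndex = i, fs = clip@fs,
        data = clip@data[, (i * d + 1L):((i + 1L) * d), drop = FALSE])
  })
}

#' Map one EEG segment channel to a CWT scalogram image
#'
#' Computes Morlet wavelet power `|W(scale, t)|^2` on `nScales` log-spaced
#' center frequencies (descending row order), then applies, in order: log1p
#' compression, resize to `resizeTo` (area-average down / bilinear up),
#' per-image z-scoring -- each only if enabled in `cfg`. Without resize the
#' output is h x d for a d-sample input.
#'
#' @param signal numeric vector (one channel of one segment, microvolts).
#' @param fs sampling rate, Hz.
#' @param cfg a [ScalogramConfig-class]; `fMax` must be <= `fs / 2`.
#' @return numeric matrix with attribute `"freqs"` (row center frequencies,
#'   Hz, descending).
#' @export
cwtScalogram <- function(signal, fs, cfg = scalogramConfig()) {
  if (!all(is.finite(signal))) stopData("signal contains NaN/Inf")
  if (cfg@fMax > fs / 2 + 1e-9)
    stopConfig("fMax exceeds the Nyquist frequency fs/2")
  freqs <- scalogramFreqs(cfg)
  img <- cwtPower(signal, fs, freqs, cfg@omega0)
  if (cfg@logPower) img <- log1p(img)
  if (length(cfg@resizeTo) == 2L)
    img <- resizeMatrix(img, cfg@resizeTo[1], cfg@resizeTo[2])
  if (cfg@normalize) {
    s <- sd(img)
    img <- if (s > 0) (img - mean(img)) / s else img * 0
  }
  structure(img, freqs = scalogramFreqs(cfg, nrow(img)))
}

#' Convert a clip into per-segment scalogram stacks
#'
#' Applies [segmentClip()] then [cwtScalogram()] to every channel of every
#' segment, independently per channel. A 10-min, 400 Hz, 16-channel clip with
#' no resize yields 60 stacks of 16 images of 100 x 4000.
#'
#' @param clip an [EEGClip-class].
#' @param cfg a [ScalogramConfig-class].
#' @param segLenS segment duration in seconds (default 10).
#' @return ordered list of [ScalogramStack-class], one per segment.
#' @export
clipToScalograms <- function(clip, cfg = scalogramConfig(), segLenS = 10) {
  segs <- segmentClip(clip, segLenS)
  lapply(segs, function(seg) {
    imgs <- lapply(seq_len(nrow(seg@data)), function(ch)
      cwtScalogram(seg@data[ch, ], seg@fs, cfg))
    freqs <- attr(imgs[[1]], "freqs")
    imgs <- lapply(imgs, function(m) { attributes(m) <- list(dim = dim(m)); m })
    new("ScalogramStack", subjectId = seg@subjectId, clipId = seg@clipId,
        label = seg@label, segmentIndex = seg@segmentIndex,
        channelNames = clip@channelNames, freqs = freqs, images = imgs)
  })
}

#' Build a model-ready scalogram dataset from a clip collection
#'
#' Converts every clip to scalogram stacks and packs them into one numeric
#' array `x` of shape (segments, channels, H, W) plus a metadata frame with
#' one row per segment (subject, clip, segment index, label, segment duration
#' in seconds). This is the tensor consumed by [trainMViT()] and
#' [evaluateModel()].
#'
#' @param clips list of [EEGClip-class] (all with the same channel count and
#'   sampling rate).
#' @param cfg a [ScalogramConfig-class].
#' @param segLenS segment duration in seconds.
#' @return list with elements `x` (4-d array), `meta` (data.frame), `freqs`.
#' @export
scalogramDataset <- function(clips, cfg = scalogramConfig(), segLenS = 10) {
  stopifnot(length(clips) >= 1L)
  stacksPerClip <- lapply(clips, clipToScalograms, cfg = cfg, segLenS = segLenS)
  stacks <- do.call(c, stacksPerClip)
  nSeg <- length(stacks)
  N <- nChannels(stacks[[1]])
  hw <- dim(stacks[[1]]@images[[1]])
  x <- array(0, c(nSeg, N, hw[1], hw[2]))
  for (i in seq_len(nSeg))
    for (b in seq_len(N))
      x[i, b, , ] <- stacks[[i]]@images[[b]]
  meta <- data.frame(
    subjectId = vapply(stacks, subjectId, character(1)),
    clipId = vapply(stacks, clipId, character(1)),
    segmentIndex = vapply(stacks, segmentIndex, integer(1)),
    label = vapply(stacks, clipLabel, character(1)),
    segDurS = segLenS,
    stringsAsFactors = FALSE
  )
  list(x = x, meta = meta, freqs = stacks[[1]]@freqs)
}
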