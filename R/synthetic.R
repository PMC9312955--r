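#' SynthConfig: parameters of the synthetic EEG generator
#'
#' The generator emulates the statistical contrast the classifier relies on:
#' interictal clips are per-channel 1/f (pink) noise with a per-subject gain;
#' preictal clips are the *same* background (matched RNG streams) plus a
#' band-limited oscillation whose RMS envelope ramps linearly from 0 at clip
#' start to `snr` times the background RMS at clip end, plus Poisson-timed
#' biphasic transient bursts. With `snr = 0` the preictal signature is absent
#' and preictal clips are bit-identical to their matched interictal clips.
#'
#' @slot nSubjects number of subjects.
#' @slot clipsPerClass clips per class per subject.
#' @slot nChannels channels per clip.
#' @slot fs sampling rate, Hz; must exceed twice the upper signature band edge.
#' @slot clipLenS clip duration in seconds; `clipLenS * fs` must be integer.
#' @slot snr signature amplitude as a multiple of background RMS (>= 0).
#' @slot sigBand numeric(2), (f_lo, f_hi) in Hz of the preictal oscillation.
#' @slot burstRate transient bursts per minute in preictal clips.
#' @slot seed integer master seed; every (subject, clip, channel) stream is
#'   derived from it with [mixSeed()].
#'
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(
    nSubjects = "integer", clipsPerClass = "integer", nChannels = "integer",
    fs = "numeric", clipLenS = "numeric", snr = "numeric",
    sigBand = "numeric", burstRate = "numeric", seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@clipsPerClass < 1L) msg <- c(msg, "clipsPerClass must be >= 1")
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@snr < 0) msg <- c(msg, "snr must be >= 0")
  if (length(object@sigBand) != 2L || object@sigBand[1] <= 0 ||
      object@sigBand[1] >= object@sigBand[2])
    msg <- c(msg, "sigBand must be (f_lo, f_hi) with 0 < f_lo < f_hi")
  if (object@fs <= 2 * object@sigBand[2])
    msg <- c(msg, "fs must exceed 2 * upper signature band edge")
  n <- object@clipLenS * object@fs
  if (abs(n - round(n)) > 1e-9)
    msg <- c(msg, "clipLenS * fs must be an integer sample count")
  if (object@burstRate < 0) msg <- c(msg, "burstRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SynthConfig
#'
#' Defaults are the package's standard benchmark conditions: 4 subjects with
#' 10 clips per class of 120 s, 4 channels at 100 Hz, an 18-24 Hz preictal
#' signature at snr 2, and 6 bursts per minute.
#'
#' @param nSubjects,clipsPerClass,nChannels,fs,clipLenS,snr,sigBand,burstRate,seed
#'   see [SynthConfig-class].
#' @return a validated [SynthConfig-class] object.
#' @export
synthConfig <- function(nSubjects = 4, clipsPerClass = 10, nChannels = 4,
                        fs = 100, clipLenS = 120, snr = 2,
                        sigBand = c(18, 24), burstRate = 6, seed = 1L) {
  tryCatch(
    new("SynthConfig", nSubjects = as.integer(nSubjects),
        clipsPerClass = as.integer(clipsPerClass),
        nChannels = as.integer(nChannels), fs = as.numeric(fs),
        clipLenS = as.numeric(clipLenS), snr = as.numeric(snr),
        sigBand = as.numeric(sigBand), burstRate = as.numeric(burstRate),
        seed = as.integer(seed)),
    error = function(e) stopConfig(conditionMessage(e)))
}

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(paste0("SynthConfig: %d subjects x 2 x %d clips, %d ch @ %g Hz,",
                     " %g s\n  snr %g in [%g, %g] Hz, %g bursts/min, seed %d\n"),
              object@nSubjects, object@clipsPerClass, object@nChannels,
              object@fs, object@clipLenS, object@snr, object@sigBand[1],
              object@sigBand[2], object@burstRate, object@seed))
})

# Unit-RMS pink (1/f) noise of length n: white Gaussian noise whose spectrum
# is shaped by 1/sqrt(f) with a 0.1 Hz floor; the DC component is zeroed.
pinkNoise <- function(n, fs) {
  w <- rnorm(n)
  W <- fft(w)
  f <- fs * pmin(0:(n - 1), n - (0:(n - 1))) / n
  g <- 1 / sqrt(pmax(f, 0.1))
  g[1] <- 0
  x <- Re(fft(W * g, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Unit-RMS band-limited Gaussian noise: white noise restricted to
# [fLo, fHi] by a spectral mask.
bandNoise <- function(n, fs, fLo, fHi) {
  w <- rnorm(n)
  W <- fft(w)
  f <- fs * pmin(0:(n - 1), n - (0:(n - 1))) / n
  W[f < fLo | f > fHi] <- 0
  x <- Re(fft(W, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Biphasic burst kernel: one positive and one negative half-sine lobe over
# `durS` seconds (default 70 ms), peak amplitude `amp`.
burstKernel <- function(fs, amp, durS = 0.07) {
  k <- max(2L, round(durS * fs))
  t <- seq_len(k) / k
  amp * sin(2 * pi * t)
}

# Preictal signature for one channel: band-limited oscillation with a linear
# 0 -> snr * bgRms RMS envelope plus Poisson-timed bursts at 3 * bgRms peak
# amplitude. Returns a zero vector when snr == 0.
preictalSignature <- function(cfg, bgRms, seedOsc, seedBurst) {
  n <- as.integer(round(cfg@clipLenS * cfg@fs))
  if (cfg@snr == 0) return(numeric(n))
  osc <- localSeed(seedOsc, bandNoise(n, cfg@fs, cfg@sigBand[1], cfg@sigBand[2]))
  ramp <- (seq_len(n) - 1) / (n - 1)
  sig <- ramp * cfg@snr * bgRms * osc
  kern <- burstKernel(cfg@fs, 3 * bgRms)
  localSeed(seedBurst, {
    nb <- rpois(1, cfg@burstRate * cfg@clipLenS / 60)
    if (nb > 0) {
      starts <- floor(runif(nb, 0, n - length(kern))) + 1
      for (s0 in starts) {
        idx <- s0:(s0 + length(kern) - 1)
        sig[idx] <- sig[idx] + kern
      }
    }
  })
  sig
}

#' Generate a labeled synthetic EEG dataset
#'
#' Produces `nSubjects x 2 x clipsPerClass` [EEGClip-class] objects. For each
#' subject, a scalar gain is drawn log-uniformly in [0.7, 1.4] (inter-subject
#' amplitude shift, so that leave-one-subject-out evaluation faces a domain
#' shift). Interictal clip j of a subject is pink-noise background; preictal
#' clip j is the *same* background plus the preictal signature (matched
#' pairs). The output is fully determined by `cfg`, independent of the
#' caller's RNG state.
#'
#' @param cfg a [SynthConfig-class].
#' @return a list of [EEGClip-class] objects, interictal and preictal clips
#'   interleaved per subject.
#' @seealso [synthConfig()], [writeDataset()]
#' @export
generateDataset <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  v <- validObject(cfg, test = TRUE)
  if (!isTRUE(v)) stopConfig(paste(v, collapse = "; "))
  n <- as.integer(round(cfg@clipLenS * cfg@fs))
  clips <- vector("list", cfg@nSubjects * 2L * cfg@clipsPerClass)
  k <- 0L
  for (s in seq_len(cfg@nSubjects)) {
    gain <- localSeed(mixSeed(cfg@seed, s, 0, 0, 0),
                      exp(runif(1, log(0.7), log(1.4))))
    sid <- sprintf("S%02d", s)
    for (j in seq_len(cfg@clipsPerClass)) {
      bg <- matrix(0, cfg@nChannels, n)
      pre <- matrix(0, cfg@nChannels, n)
      for (ch in seq_len(cfg@nChannels)) {
        b <- gain * localSeed(mixSeed(cfg@seed, s, j, ch, 1), pinkNoise(n, cfg@fs))
        bg[ch, ] <- b
        pre[ch, ] <- b + preictalSignature(cfg, gain,
                                           mixSeed(cfg@seed, s, j, ch, 2),
                                           mixSeed(cfg@seed, s, j, ch, 3))
      }
      clips[[k <- k + 1L]] <- eegClip(bg, cfg@fs, "interictal", sid,
                                      sprintf("%s_int_%03d", sid, j))
      clips[[k <- k + 1L]] <- eegClip(pre, cfg@fs, "preictal", sid,
                                      sprintf("%s_pre_%03d", sid, j))
    }
  }
  clips
}

#' Write a clip collection to a directory with a JSON manifest
#'
#' Each clip is written through [writeClip()] (competition-style container +
#' JSON sidecar) and a `manifest.json` is emitted listing subject, clip id,
#' label, sampling rate, channel count and duration, so synthetic and real
#' data take the identical downstream path.
#'
#' @param clips list of [EEGClip-class].
#' @param dir output directory; its parent must exist.
#' @param provenance character(1) recorded in the manifest, e.g. "synthetic".
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(clips, dir, provenance = "synthetic") {
  if (!dir.exists(dirname(dir)))
    stopData("parent directory does not exist: ", dirname(dir))
  dir.create(dir, showWarnings = FALSE)
  rows <- lapply(clips, function(cl) {
    path <- file.path(dir, paste0(cl@clipId, ".mat"))
    writeClip(cl, path)
    list(subject = cl@subjectId, clip_id = cl@clipId, label = cl@label,
         fs = cl@fs, n_channels = nrow(cl@data),
         duration_s = ncol(cl@data) / cl@fs, file = basename(path))
  })
  manifest <- list(provenance = provenance, n_clips = length(clips),
                   clips = rows)
  mpath <- file.path(dir, "manifest.json")
  writeJson(manifest, mpath)
  invisible(mpath)
}

#' Read a clip directory written by [writeDataset()]
#'
#' @param dir directory containing `manifest.json` and clip containers.
#' @return a list of [EEGClip-class].
#' @export
readDataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stopData("no manifest.json in ", dir)
  manifest <- readJson(mpath)
  lapply(manifest$clips$file, function(f) readCompetitionClip(file.path(dir, f)))
}
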