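rawScalCfg <- function(nScales = 100, fMin = 0.5, fMax = 50) {
  scalogramConfig(nScales = nScales, fMin = fMin, fMax = fMax,
                  logPower = FALSE, resizeTo = NULL, normalize = FALSE)
}

test_that("segmentation follows the 10-min clip arithmetic", {
  # 10-min invasive clip at 400 Hz: 60 segments of 16 x 4000
  clip <- eegClip(matrix(0, 16, 240000), 400, "preictal", "P1", "c1")
  segs <- segmentClip(clip)
  expect_length(segs, 60L)
  expect_identical(dim(clipData(segs[[1]])), c(16L, 4000L))
  expect_identical(vapply(segs, segmentIndex, integer(1)), 0:59)
  expect_true(all(vapply(segs, clipLabel, character(1)) == "preictal"))

  # surface EEG at 256 Hz: 10-s segments of 2560 samples per channel
  clip2 <- eegClip(matrix(rnorm(2 * 153600), 2, 153600), 256)
  segs2 <- segmentClip(clip2)
  expect_length(segs2, 60L)
  expect_identical(ncol(clipData(segs2[[1]])), 2560L)
  # contiguous, non-overlapping: concatenation reproduces the clip
  expect_identical(do.call(cbind, lapply(segs2, clipData)), clipData(clip2))

  # exactly one segment: identity; shorter than one segment: error
  clip3 <- eegClip(matrix(rnorm(300), 3, 100), 10)
  one <- segmentClip(clip3)
  expect_length(one, 1L)
  expect_identical(clipData(one[[1]]), clipData(clip3))
  expect_error(segmentClip(eegClip(matrix(0, 1, 50), 10)),
               class = "mvitDataError")
  # 25-min clip: floor division, remainder dropped
  expect_length(segmentClip(eegClip(matrix(0, 1, 150 * 10), 10), 60), 2L)
})

test_that("scalograms have shape h x d and vanish on zero input", {
  cfg <- rawScalCfg()
  img <- cwtScalogram(rep(0, 4000), 400, cfg)
  expect_identical(dim(img), c(100L, 4000L))
  expect_true(all(img == 0))
  fr <- attr(img, "freqs")
  expect_length(fr, 100L)
  expect_true(all(diff(fr) < 0)) # descending frequency rows
  expect_equal(fr[1], 50)
  expect_equal(fr[100], 0.5)
  expect_error(cwtScalogram(c(1, NaN, 3), 400, cfg), class = "mvitDataError")
  expect_error(cwtScalogram(rnorm(100), 80, cfg), class = "mvitConfigError")
})

test_that("a pure tone localizes to the nearest scale and matches a direct
           time-domain convolution", {
  fs <- 400
  cfg <- rawScalCfg(nScales = 40)
  tt <- (0:(2 * fs - 1)) / fs
  x <- cos(2 * pi * 10 * tt)
  img <- cwtScalogram(x, fs, cfg)
  fr <- attr(img, "freqs")
  fpk <- fr[which.max(rowMeans(img))]
  binFactor <- exp(abs(diff(log(fr)))[1])
  expect_lt(max(fpk / 10, 10 / fpk), binFactor)

  # direct convolution oracle: explicitly sampled Morlet, time-domain sum
  sub <- c(5L, 20L, 35L) # three scales across the grid
  n <- length(x)
  for (j in sub) {
    s <- 6 / (2 * pi * fr[j])
    K <- ceiling(6 * s * fs)
    kk <- (-K:K) / fs
    psi <- pi^(-1 / 4) / sqrt(s) * exp(1i * 6 * kk / s - (kk / s)^2 / 2)
    xp <- c(rep(0, K), x, rep(0, K))
    direct <- vapply(seq_len(n), function(t0)
      Mod(sum(xp[t0:(t0 + 2 * K)] * Conj(psi)) / fs)^2, numeric(1))
    expect_lt(max(abs(img[j, ] - direct)) / max(direct), 1e-6)
  }
})

test_that("power scales quadratically and channels are independent", {
  cfg <- rawScalCfg(nScales = 12, fMin = 2)
  x <- rnorm(500)
  a <- cwtScalogram(x, 100, cfg)
  b <- cwtScalogram(3 * x, 100, cfg)
  expect_equal(as.numeric(b), as.numeric(9 * a), tolerance = 1e-10)
  expect_true(all(a >= 0))

  # channel permutation permutes the stack images identically
  dat <- matrix(rnorm(3 * 1000), 3, 1000)
  clip <- eegClip(dat, 100, "interictal")
  perm <- c(3L, 1L, 2L)
  clipP <- eegClip(dat[perm, ], 100, "interictal")
  st <- clipToScalograms(clip, cfg)[[1]]
  stP <- clipToScalograms(clipP, cfg)[[1]]
  expect_identical(stackImages(stP), stackImages(st)[perm])
})

test_that("resampling integrates area when downsampling and z-scoring
           standardizes images", {
  # area weights: integer-factor downsample equals block means
  m <- matrix(rnorm(8 * 12), 8, 12)
  small <- SeizureMViT:::resizeMatrix(m, 4, 6)
  oracle <- matrix(0, 4, 6)
  for (i in 1:4) for (j in 1:6)
    oracle[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(small, oracle, tolerance = 1e-12)
  # constant images are fixed points of resampling (any factor)
  cm <- matrix(7, 10, 10)
  expect_equal(as.numeric(SeizureMViT:::resizeMatrix(cm, 3, 17)),
               rep(7, 3 * 17), tolerance = 1e-12)
  # upsampling interpolates within the input range
  up <- SeizureMViT:::resizeMatrix(matrix(c(0, 1), 1, 2), 1, 8)
  expect_true(all(up >= 0 & up <= 1))
  expect_true(all(diff(as.numeric(up)) >= 0))

  # full pipeline: resized shape, non-negativity before z-score, z-score stats
  cfg <- scalogramConfig(nScales = 16, fMin = 2, fMax = 50,
                         resizeTo = c(16, 32), normalize = FALSE)
  img <- cwtScalogram(rnorm(1000), 100, cfg)
  expect_identical(dim(img), c(16L, 32L))
  expect_true(all(img >= 0))
  cfgZ <- scalogramConfig(nScales = 16, fMin = 2, fMax = 50,
                          resizeTo = c(16, 32), normalize = TRUE)
  imgZ <- cwtScalogram(rnorm(1000), 100, cfgZ)
  expect_equal(mean(imgZ), 0, tolerance = 1e-12)
  expect_equal(sd(imgZ), 1, tolerance = 1e-12)
})

test_that("clip_to_scalograms composes segmentation and per-channel CWT", {
  cfg <- scalogramConfig(nScales = 8, fMin = 2, fMax = 50,
                         resizeTo = c(8, 16))
  clip <- eegClip(matrix(rnorm(2 * 3000), 2, 3000), 100, "preictal", "S1", "c")
  stacks <- clipToScalograms(clip, cfg)
  expect_length(stacks, 3L) # 30 s -> 3 segments
  expect_identical(nChannels(stacks[[1]]), 2L)
  expect_identical(vapply(stacks, clipLabel, character(1)), rep("preictal", 3))
  # single-channel clip: the stack image equals cwtScalogram of that channel
  clip1 <- eegClip(clip@data[1, , drop = FALSE], 100, "preictal", "S1", "c")
  st1 <- clipToScalograms(clip1, cfg)[[2]]
  seg <- segmentClip(clip1)[[2]]
  ref <- cwtScalogram(clipData(seg)[1, ], 100, cfg)
  expect_equal(stackImages(st1)[[1]], matrix(ref, nrow(ref), ncol(ref)),
               tolerance = 1e-12)

  # dataset packing: one row and one tensor slice per segment
  ds <- scalogramDataset(list(clip), cfg)
  expect_identical(dim(ds$x), c(3L, 2L, 8L, 16L))
  expect_identical(nrow(ds$meta), 3L)
  expect_identical(ds$meta$segmentIndex, 0:2)
  expect_identical(unique(ds$meta$segDurS), 10)
  expect_equal(ds$x[2, 1, , ], stackImages(clipToScalograms(clip, cfg)[[2]])[[1]])
})
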