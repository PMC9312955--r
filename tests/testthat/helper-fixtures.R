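# Shared fixtures: small configurations used across test files. Everything is
# generated in code; no stored data.

# scalogram config small enough for fast model tests
smallScalCfg <- function() {
  scalogramConfig(nScales = 16, fMin = 2, fMax = 50, resizeTo = c(16, 32))
}

# matching small model: 16x32 images, 8x8 patches -> L = 8 tokens
smallModelCfg <- function(nBranches = 2, ...) {
  mvitConfig(nBranches = nBranches, imageShape = c(16, 32),
             patchShape = c(8, 8), embedDim = 16, depth = 1, nHeads = 2,
             mlpHidden = 16, dropout = 0, ...)
}

# tiny labeled scalogram dataset (2 subjects, 2-channel 30-s clips)
tinyDataset <- function(seed = 1, nSubjects = 2, clipsPerClass = 3,
                        snr = 2, clipLenS = 30, nChannels = 2) {
  clips <- generateDataset(synthConfig(
    nSubjects = nSubjects, clipsPerClass = clipsPerClass,
    nChannels = nChannels, fs = 100, clipLenS = clipLenS, snr = snr,
    sigBand = c(18, 24), burstRate = 6, seed = seed))
  scalogramDataset(clips, smallScalCfg())
}

# tiny config whose whole parameter vector is cheap enough for full
# finite-difference sweeps
gradCheckCfg <- function() {
  mvitConfig(nBranches = 2, imageShape = c(4, 4), patchShape = c(2, 2),
             embedDim = 4, depth = 1, nHeads = 2, mlpHidden = 4,
             headHidden = 4, dropout = 0)
}

# band power in [fLo, fHi] Hz via the smoothed periodogram -- the spectral
# oracle used against the generator (independent of the wavelet code)
bandPower <- function(x, fs, fLo, fHi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                          taper = 0, detrend = FALSE)
  sel <- sp$freq >= fLo & sp$freq <= fHi
  mean(sp$spec[sel])
}

# seeded permutation used by the label-permutation null test
localSeedPermute <- function(x, seed) {
  set.seed(seed)
  sample(x)
}
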