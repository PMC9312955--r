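---
title: "Methods: scalogram-based seizure prediction with a multi-channel vision transformer"
author: "SeizureMViT authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scalogram-based seizure prediction with a multi-channel vision transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeizureMViT)
```

## The problem and the model

Seizure prediction from EEG is cast here as binary classification of short
EEG segments into **preictal** (recorded in the hour before a seizure onset,
minus a five-minute offset) versus **interictal** (baseline activity more
than four hours from any seizure). The unit of labeling is the 10-minute
clip, the convention of the public scalp (256 Hz, 23 channels) and invasive
(400 Hz, 16 channels) seizure-prediction corpora; the unit of *decision* is
the 10-second segment, so each clip contributes 60 labeled examples.

The pipeline has three stages:

1. **Segmentation.** Each clip is cut into non-overlapping 10-s segments
   (2560 samples per channel at 256 Hz; 4000 at 400 Hz). Segments inherit
   the clip label; partial trailing segments are dropped.

2. **Time-frequency mapping.** Each segment channel is transformed into a
   scalogram: Morlet wavelet power $|W(s,t)|^2$ evaluated on a grid of
   log-spaced center frequencies. The wavelet is the analytic Morlet
   $\psi_s(t) = s^{-1/2}\pi^{-1/4} e^{i\omega_0 t/s} e^{-t^2/(2s^2)}$ with
   shape parameter $\omega_0 = 6$, the community default for EEG
   time-frequency analysis; the scale of center frequency $f$ is
   $s = \omega_0 / (2\pi f)$.

3. **Classification.** A multi-channel vision transformer: each of the $N$
   channels has its own transformer-encoder branch. A branch splits its
   $H \times W$ scalogram into non-overlapping $P_h \times P_w$ patches
   ($L = HW/(P_h P_w)$ tokens), projects each flattened patch linearly into
   a $D_e$-dimensional embedding, adds learned position embeddings, and
   applies a stack of pre-norm encoder blocks
   $u = x + \mathrm{MSA}(\mathrm{LN}(x))$,
   $y = u + \mathrm{MLP}(\mathrm{LN}(u))$ with multi-head scaled dot-product
   attention and a GELU MLP. The branch feature is the mean over its $L$
   output tokens (no class token; the simplest reading of a design that
   "aggregates" branch outputs). Features are concatenated in channel order
   and classified by a one-hidden-layer GELU MLP with a softmax output.

The forward pass, backpropagation, Adam, dropout, layer normalization and
label smoothing are implemented in this package (R reference implementation
plus an RcppArmadillo mirror used for training; the two are asserted equal
in the test suite, and the analytic gradient is checked against finite
differences).

## Design decisions where the architecture was open

Several choices are not dictated by the architecture sketch above and are
therefore explicit, recorded decisions:

* **Rectangular patches.** Square $P \times P$ patches generalize to
  $P_h \times P_w$ because the practical scalogram images are non-square.
* **Per-branch weights.** Each channel's branch has its own projection,
  position embeddings and encoder weights (`shareBranchWeights = FALSE`);
  channels are distinct inputs. A shared-weight switch covers the
  alternative reading.
* **Mean-pooled branch features.** Pooling over tokens, rather than a class
  token, implements the aggregation.
* **Initialization.** Truncated normal (sd 0.02, clipped at 2 sd) for all
  projections and position embeddings; zeros for biases and layer-norm
  offsets; ones for layer-norm gains. Seeded.
* **Scale grid.** `scalogramConfig()` defaults to 100 log-spaced center
  frequencies on [0.5, 50] Hz (clinical EEG bands). Nothing forces a
  particular grid; the scalogram config is serialized with every run.

## Scalogram numerics

The CWT is defined as the discrete cross-correlation of the zero-padded
signal with the sampled wavelet, truncated at $|t| \le 6s$ (the Gaussian
envelope is below $2\times10^{-8}$ there). The implementation evaluates the
same sum with FFTs (one forward FFT of the padded signal and one batched
inverse FFT across all scales); it is numerically identical to the direct
time-domain sum up to float round-off, which the tests assert at relative
$10^{-6}$ against an independently coded direct convolution. Edges are
zero-padded and the cone of influence is *not* masked — the simplest
reproducible convention; per-segment transforms mean edge effects are
identical for both classes.

The image pipeline after the raw $h \times d$ power matrix is, in order:

1. `log1p` compression (power spans orders of magnitude);
2. resize to the model's input shape $(H, W)$. Downsampling uses
   **area-weighted averaging** (each output cell is the overlap-weighted
   mean of the input cells it covers); upsampling uses bilinear
   interpolation. Area averaging, rather than point-sampled interpolation,
   is the correct decimation for power images: a 70-ms transient or a
   narrow-band power ramp contributes its full energy to the coarse image
   instead of being hit-or-miss point-sampled.
3. per-image z-scoring, which removes inter-subject amplitude scale — the
   main domain shift a leave-one-subject-out split must survive.

## The synthetic data generator

The generator exists so that the full pipeline is testable without any
external recordings. It emulates the one statistical property the method
relies on: preictal segments carry more power than interictal segments in
some time-frequency region.

* **Background**: per-channel pink noise (white Gaussian noise whose
  spectrum is shaped by $1/\sqrt{f}$ with a 0.1 Hz floor), normalized to
  unit RMS, scaled by a per-subject gain drawn log-uniformly in
  [0.7, 1.4] — so held-out subjects present a genuine amplitude shift.
* **Preictal signature**: (i) band-limited Gaussian noise in
  `sigBand` (default 18–24 Hz) whose RMS envelope ramps linearly from 0 at
  clip start to `snr` × background RMS at clip end, and (ii) Poisson-timed
  biphasic bursts (70 ms, one positive and one negative half-sine lobe,
  peak 3 × background RMS) at `burstRate` per minute (default 6 — roughly
  one burst per 10-s segment in expectation, so segment-level evidence is
  present but not guaranteed).
* **Matched pairs**: preictal clip *j* of a subject adds the signature to
  the *same* background realization as interictal clip *j* (per
  (subject, clip, channel) RNG streams derived by integer hashing from the
  master seed). With `snr = 0` the signature is absent entirely and the two
  classes are bit-identical, which makes the null control exact: the
  pooled score multisets of the two classes coincide and the tie-aware AUC
  is 0.5 by construction.

What the generator does **not** emulate: real seizure dynamics, artifacts
(EMG, eye blinks, electrode pops), non-stationary background drift, montage
correlations between channels. Passing the synthetic benchmark therefore
demonstrates that the pipeline is implemented correctly and can learn a
spectro-temporal contrast under subject shift — not that it reproduces
clinical performance on real EEG.

## Training protocol

Training minimizes class-weighted cross-entropy with label smoothing 0.1
using Adam (learning rate 2e-3), a linear warmup over the first 4 epochs,
and multiplicative decay 0.92 per epoch thereafter; minibatch 32, at most
35 epochs. The validation split is drawn at **clip** level (stratified by
subject and label; 20% of the training subjects' clips), never at segment
level, so segments of one clip can never straddle the split. After each
epoch the validation AUC is computed; the checkpoint with the best
validation AUC is returned and training stops early after 10 epochs without
improvement. Warmup epochs are excluded from checkpoint selection and the
patience count — the model has not yet trained at its target learning rate,
and an epoch-1 model that happens to rank validation segments well is still
uncalibrated at the 0.5 decision threshold.

Label smoothing matters here for a subtle reason: with hard targets the
converged network saturates its probabilities, and segments with weak
evidence (the early-clip preictal segments, where the synthetic ramp is
near zero) end up on the wrong side of the fixed 0.5 threshold even when
the ranking (AUC) is good. Smoothed targets keep the probabilities
calibrated as training converges, so sensitivity at the fixed threshold
improves together with the validation AUC instead of trading off against
it.

Class weights are inverse-frequency (a no-op on the balanced synthetic
data, but it keeps all interictal data rather than undersampling when
classes are imbalanced). All randomness — initialization, the validation
split, shuffling, dropout — derives from the training seed, and two runs
with the same seed produce bit-identical checkpoints.

## Evaluation

Each 10-s segment is one decision; there is no alarm post-processing.
At threshold $\tau$ (default 0.5, preictal iff $p \ge \tau$):
SENS $= TP/(TP+FN)$, SPEC $= TN/(TN+FP)$, ACC $= (TP+TN)/n$, and the false
positive rate per hour divides FP by the interictal hours evaluated (each
10-s segment contributes 1/360 h). The AUC is the tie-aware Mann–Whitney
concordance probability, equal to the trapezoidal area under the ROC curve
and invariant under monotone transforms of the scores. Metrics whose
defining class is absent are reported as `NA`, never as zero.

Leave-one-subject-out cross-validation trains one model per subject on all
other subjects' segments and evaluates on the held-out subject; the pooled
report is computed over the union of the per-fold prediction sets, and the
pooled confusion counts are exactly the sums of the fold counts.

## Problem sizes used by the bundled experiments

The package's standard benchmark (the defaults of `synthConfig()`) uses
4 subjects × (10 preictal + 10 interictal) clips of 120 s, 4 channels at
100 Hz, snr 2 in 18–24 Hz — 960 segments in total — with 32 wavelet scales
on [2, 50] Hz resized to 32 × 64 images, 8 × 8 patches, embedding dimension
32, depth 2, 2 heads. Nothing below 2 Hz is informative for an 18–24 Hz
signature at these clip lengths, and 32 native scales match the 32-row
model input so the frequency axis is not resampled. These sizes exercise
every stage of the method at desk scale; the architecture and the code path
are identical for full-scale data (e.g. 23-channel, 256 Hz EDF recordings),
only the configuration objects change.

## Known limitations

* The synthetic benchmark is a correctness and capability check, not a
  clinical claim; see the generator's non-goals above.
* Attention is quadratic in the token count; very large scalograms should
  be resized or patched more coarsely.
* The EDF reader covers ordinary 16-bit EDF signals (uniform sampling rate
  across retained channels); EDF+ annotation authoring is out of scope, and
  clip labeling is taken from explicit interval specifications rather than
  re-derived from seizure annotations.
* The MAT v5 container support covers the subset used by competition-style
  clip files (top-level numeric/character matrices, zlib-compressed
  elements on read); it is not a general MAT-file implementation.
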