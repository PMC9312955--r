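Package: SeizureMViT
Title: Multi-Channel Vision Transformer for EEG Seizure Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for preictal versus interictal EEG
    classification. Multichannel EEG clips (EDF recordings or 10-minute
    competition-style clip containers) are split into 10-second segments,
    each channel is mapped to a continuous-wavelet-transform (Morlet)
    scalogram image, and the per-channel scalograms are classified by a
    multi-channel vision transformer: one patch-embedding + pre-norm
    transformer-encoder branch per EEG channel, with branch features
    aggregated into an MLP head. Includes a seeded synthetic EEG generator
    (1/f background, band-limited preictal power ramp, transient bursts),
    leave-one-subject-out cross-validation, and a metric suite
    (sensitivity, specificity, accuracy, false positives per interictal
    hour, AUC). Model training (Adam, dropout, layer normalization,
    multi-head self-attention and its backpropagation) is implemented in
    base R matrix algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
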