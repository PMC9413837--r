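Package: e2ennet
Title: End-to-End EEG Emotion Recognition with Depthwise-Separable
    Convolutions and LSTMs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the E2ENNet architecture for emotion recognition
    from raw multi-channel EEG: per-second baseline removal and 1-s epoch
    slicing, a compact convolutional front-end (temporal, depthwise and
    depthwise-separable convolutions with batch normalisation), a
    two-layer (peephole) LSTM back-end and a softmax classifier, trained
    with Adam under subject-dependent trial-wise cross-validation.
    Includes differential-entropy and band-power feature extraction as
    alternative model inputs, ablation variants, a synthetic
    emotional-EEG generator with class-conditional band-power structure,
    readers and writers for MAT-v5 and an HDF5 recording layout, and a
    command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    rhdf5,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
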