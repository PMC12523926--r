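Package: olfnirs
Title: Decoding Olfactory Task Performance from Prefrontal fNIRS Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for decoding psychophysical olfactory
    task performance (threshold, discrimination, identification) from
    block-design functional near-infrared spectroscopy (fNIRS) recordings.
    Simulates dual-wavelength optical-density sessions with physiological
    noise and motion artifacts, converts optical density to hemoglobin
    concentration changes via the modified Beer-Lambert law, performs quality
    screening, zero-phase band-pass filtering, spline-based motion correction
    and stimulus-locked epoching, extracts a per-epoch feature battery
    (waveform morphology, Lempel-Ziv complexity, inter-channel mutual
    information, discrete-wavelet statistics, summary moments), and evaluates
    task-specific classifiers -- gradient-boosted trees, logistic regression,
    random forest, multilayer perceptron, and an attention-augmented 1D
    convolutional network -- under participant-grouped repeated
    cross-validation with grouped bootstrap confidence intervals and exact
    tree-based feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    ranger,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
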