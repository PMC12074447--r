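Package: fmdetect
Title: Fetal Movement Detection from Multi-Sensor Inertial Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for detecting fetal movement in
    multi-sensor maternal-abdomen inertial recordings. Generates synthetic
    trials from five tri-axial inertial measurement units (four abdominal, one
    chest reference) sharing rigid-body torso motion with localized fetal
    bursts and imperfect maternal perception; preprocesses signals with
    zero-phase bandpass filtering and functional axis alignment from
    calibration movements; labels sliding windows from perception button
    presses by fractional overlap; builds three data representations
    (hand-engineered feature vectors, raw time-series tensors, short-time
    Fourier transform spectrograms); trains and compares a random forest, a
    bidirectional long short-term memory network, and a convolutional neural
    network; and evaluates them with trial-level Monte Carlo cross-validation,
    threshold sweeps, and training-set-size sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    ranger,
    jsonlite,
    data.table,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
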