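Package: emsfilter
Title: Effect-Matched Spatial Filtering for Epoched Multi-Sensor Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Reduces epoched multi-sensor recordings (channel x sample x trial),
    such as EEG or MEG epochs, to one surrogate time course per trial by
    projecting each time sample onto a unit-norm spatial filter matched to an
    experimental effect estimated from held-out trials (effect-matched spatial
    filtering). Provides per-timepoint and stationary-template transforms under
    leave-one-out, leave-one-out-per-condition, stratified k-fold and
    leave-one-subject-out cross-validation; pluggable objective functions
    (difference of class means, windowed differences, temporal-predictor
    regression); evaluation tools (effect time courses, signal-to-noise ratio in
    decibels, SNR versus trial count, nested Gaussian naive-Bayes decoding,
    component latency and duration metrics); seeded synthetic-data generators
    with known ground truth; and an HDF5 epochs container plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rhdf5,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
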