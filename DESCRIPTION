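Package: radspectra
Title: Radiation-Response Classification of Raman Tissue Spectra
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for discriminating irradiated from
    non-irradiated tumour-tissue Raman spectra. Provides a hierarchical
    synthetic-spectrum generator (dose-responsive Lorentzian bands over a
    fluorescence baseline, with mouse/section/map random effects), a spectral
    preprocessing chain (cosmic-ray removal, Savitzky-Golay smoothing,
    iteratively-reweighted polynomial baseline subtraction, total-area
    normalization), a one-dimensional convolutional neural network classifier
    trained with Adam and best-validation-epoch selection, group- and
    basis-restricted non-negative matrix factorization onto a frozen library
    of pure-biochemical spectra plus one free factor, a random-forest
    classifier with permutation (mean-decrease-accuracy) importance, and a
    validation harness covering random splits, leave-one-subject-out schemes,
    confusion-matrix metrics, multi-run aggregation and Wilcoxon model
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), quadprog, withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
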