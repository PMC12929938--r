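Package: poreDelay
Title: Classification of Delayed Nanopore Translocation Events
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting target-bound ("delayed") translocation
    events in nanopore ionic-current recordings from DNA-barcoded probes.
    Implements three complementary classifiers: a moving-standard-deviation
    (MSD) threshold rule on binned, min-max-normalized traces; an
    instantaneous spectral-entropy rule on spectrogram frames; and a small
    LeNet-style convolutional network trained on grayscale renderings of the
    raw traces, with Grad-CAM saliency maps. Includes Smith-Waterman barcode
    read filtering, confusion-matrix and ROC evaluation, min-max radar
    scaling, MAD outlier gating, baseline correction, Hill-equation
    dose-response fitting, and a seeded synthetic event simulator that
    emulates delayed, non-delayed, and noisy-delay signal classes for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    minpack.lm,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
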