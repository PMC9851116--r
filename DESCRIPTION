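Package: fvepnet
Title: Multi-Branch Convolutional Classification and Out-of-Distribution
    Detection for Flash Visual Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying flash visual evoked potential (FVEP)
    sweeps and detecting out-of-distribution recordings. Implements a
    multi-input 1D convolutional network with a global-convolution branch,
    a local-convolution branch, a manual-feature branch and a learned
    confidence head trained with a confidence-hinted focal loss; empirical
    mode decomposition denoising by selective IMF reconstruction;
    temporal/statistical/spectral feature extraction with variance and
    Pearson-correlation feature selection; convolutional-autoencoder
    pretraining of the local branch; classical novelty-detection baselines
    (entropy, LOF, one-class SVM, minimum covariance determinant) on the
    penultimate embedding; and a seeded synthetic FVEP generator so the
    whole pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    readr,
    stats,
    utils,
    pracma,
    e1071,
    MASS,
    jsonlite,
    yaml,
    generics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    signal,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
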