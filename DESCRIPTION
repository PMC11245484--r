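Package: ppgfatigue
Title: Fatigue Detection from Photoplethysmography with Wavelet Denoising
    and Hybrid Convolutional-Recurrent Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for two-class fatigue detection from
    single-channel photoplethysmography (PPG). Provides a seeded simulator of
    two-condition PPG cohorts with Karolinska Sleepiness Scale (KSS) and
    psychomotor vigilance (PVT) metadata, discrete-wavelet-transform shrinkage
    denoising (hard/soft thresholding with universal, SURE and minimax rules),
    window segmentation with derived heart-rate and breathing channels,
    subject-wise cross-validation planning, compact one-dimensional
    residual-network and depthwise-separable (Xception-style) convolutional
    feature extractors coupled to a bidirectional LSTM with a scaled-softmax
    head trained by stochastic gradient descent with momentum, and an
    evaluation layer with confusion matrices, rank-based AUC, per-subject
    majority voting and metric gating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
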