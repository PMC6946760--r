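Package: emgmpr
Title: Myoelectric Pattern Recognition from Multi-Channel Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An offline myoelectric pattern-recognition (MPR) pipeline for
    multi-channel surface electromyography (EMG). Provides band-pass and
    notch pre-filtering, contraction trimming, overlapped windowing, 44
    window-level signal features in the time, frequency and time-frequency
    domains (including Hjorth parameters, Higuchi's fractal dimension and
    wavelet-packet energy features), sequential forward-selection /
    backward-elimination and PCA dimensionality reduction, six classifiers
    (LDA, KNN, decision tree, Gaussian maximum likelihood, RBF-SVM and a
    two-hidden-layer MLP) under stratified 10-fold cross-validation, class
    performance matrices and timing reports, and a deterministic synthetic
    EMG session generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    rpart,
    e1071,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
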