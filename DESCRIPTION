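Package: eegauth
Title: Single-Trial EEG Biometric Authentication with EMD Features and
    Gated RBF-SVM Decoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating single-trial EEG-based
    person-authentication decoders from motor-task recordings. Implements
    EDF and array-bundle ingestion with 10-20 channel presets, zero-phase
    band-pass filtering and overlapping window segmentation; empirical
    mode decomposition with dB-based sifting stop criteria; an 18-feature
    bank per channel (Shannon, log-energy, sample and approximate
    entropies of the first four intrinsic mode functions plus multitaper
    mu- and beta-band powers); channel-dimension reduction to a fixed
    36-element vector by cross-correlation clustering or PCA; greedy beam
    forward feature selection scored by inner cross-validated SVM
    accuracy; per-user radial-basis SVM authenticators gated across two
    motor tasks; and biometric evaluation (FAR, FRR, accuracy, ROC/AUC,
    paired Wilcoxon system comparisons) against expanded imposter pools.
    A seeded synthetic-EEG cohort generator with controllable
    between-subject separability supports end-to-end testing without any
    external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
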