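Package: moca
Title: Optimal Linear Aggregation of Rank-Calibrated Binary Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines prediction scores from an ensemble of binary classifiers
    into a single linear ensemble that maximizes the signal-to-noise ratio (SNR)
    of rank-transformed predictions. Provides a supervised estimator that
    computes SNR-optimal weights from class-conditioned rank moments (a
    Fisher-discriminant analysis on within-classifier sample ranks, with
    optional greedy forward selection of base classifiers) and an unsupervised
    estimator that infers prevalence, class-mean separations and conditional
    variance sums from second- and third-order moments of unlabeled rank
    predictions via rank-one fits of the covariance matrix and the third
    central-moment tensor, valid under class-conditioned independence. Includes
    a calibrated Gaussian simulator for classifier scores with user-specified
    AUCs and conditional correlation, rank-based performance metrics (AUC,
    balanced accuracy, F1), wisdom-of-crowds and best-individual baselines,
    and a stratified cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
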