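Package: teptools
Title: Tumor-Educated Platelet RNA-Seq Cancer Classification Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a liquid-biopsy classification
    workflow for tumor-educated platelet (TEP) RNA-seq data. Provides count
    quality control and annotation-based filtering, median-of-ratios size
    factors with a closed-form negative-binomial variance-stabilizing
    transform, KEGG-style pathway feature preselection and per-sample
    pathway-grid image encoding, class-weighted gradient boosting with
    random hyperparameter search and a compact convolutional network
    trained with adadelta, plus an evaluation harness covering stratified
    splits, cross-validation, image-permutation controls, hospital-transfer
    robustness, pathway-group ablation, and importance-limited feature
    sweeps. A negative-binomial synthetic-data generator with planted
    differential signal, site effects, and ground truth supports
    parameter-recovery and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    xgboost,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
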