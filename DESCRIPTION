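Package: cuporigin
Title: Gene-Set Featurization and Ensemble Classification of Metastatic
    Cancer Origin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the primary site of origin of metastatic tumors from
    bulk transcriptomes. Per-sample expression profiles are converted into
    signed, normalized gene-set enrichment scores via an unweighted
    Kolmogorov-Smirnov running sum, which makes microarray and RNA-seq
    cohorts comparable; gene-set features that discriminate the measurement
    platform are removed by single-feature ROC AUC filtering; and a
    soft-voting ensemble of multinomial ridge regression, gradient-boosted
    trees, and an RBF-kernel support vector machine ranks candidate origin
    sites by probability. Includes evaluation protocols (top-k weighted
    accuracy, confusion matrices, stratified cross-validation, cross-platform
    transfer, feature-band sweeps), a two-platform synthetic cohort
    generator with planted class and platform signal, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    xgboost,
    e1071,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
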