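Package: rocut
Title: Optimal ROC Cut-Points by the Index of Union and Reference Criteria
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Selects optimal cut-points for a continuous diagnostic marker
    from empirical ROC coordinates using the Index of Union criterion
    (sensitivity and specificity jointly closest to the AUC) together with
    four reference criteria: the Youden index, the point closest to the
    (0,1) corner, the concordance probability, and the minimum P value
    (maximally selected chi-square) approach.  Provides population (true)
    cut-points under normal and gamma biomarker models, stratified bootstrap
    percentile confidence intervals, a Monte-Carlo engine for evaluating
    relative bias, mean squared error, and bootstrap coverage of the
    estimators, and a twofold cross-validation check of cut-point stability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
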