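Package: conformalgx
Title: Conformal Prediction for Genomic Medicine Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distribution-free uncertainty quantification for gene-expression
    based predictive models. Implements transductive and inductive conformal
    classifiers (including the label-conditional Mondrian variant), inductive
    conformal regression with absolute-residual calibration, coverage and
    adaptivity diagnostics (empirical coverage, uncertain-prediction rate,
    error-detection rate, size-stratified coverage, repeated-split coverage),
    maximum mean discrepancy permutation testing for distribution shift
    between cohorts, minimum-redundancy maximum-relevance feature selection,
    and seeded synthetic expression-cohort generators emulating binary drug
    response, three-subtype lymphoma classification under covariate shift,
    and positively skewed IC50 regression. Three end-to-end pipelines tie the
    pieces together and write fully reproducible reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
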