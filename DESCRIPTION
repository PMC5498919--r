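Package: lungpanel
Title: Serum Biomarker Panel Training and Blinded Validation for Indeterminate Pulmonary Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for building and validating serum-protein
    classifiers of indeterminate pulmonary nodules: pre-analytical stability
    screening of candidate markers across blood clotting times, elasticnet
    (lasso-dominant) penalized logistic panel training with the regularization
    penalty chosen by stratified bootstrap out-of-bag AUC, bootstrap internal
    validation, and blinded validation on an independent matched case-control
    cohort with DeLong ROC confidence intervals, paired AUC tests, and stage,
    histology and radiographic-finding subgroup analyses. Includes a synthetic
    matched case-control cohort generator so the full pipeline is exercisable
    and testable without access to restricted trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
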