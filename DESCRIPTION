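Package: seroclust
Title: Discriminative T Cell Cluster Discovery from Mass Cytometry Compositions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of mass-cytometry (CyTOF) T cell data for
    discriminating seropositive from seronegative rheumatoid arthritis:
    self-organizing-map clustering with hierarchical metaclustering,
    centered log-ratio transformation of cluster compositions,
    propensity-score based inverse probability weighting, adaptive-LASSO
    stability selection under leave-one-out cross-validation, weighted rank
    tests, and bootstrap support-vector-machine validation with a
    label-permutation null. Includes a synthetic cohort generator with
    planted cluster-abundance effects and confounded covariates so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    randomForest,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
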