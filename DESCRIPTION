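Package: bistrat
Title: Bicluster-Based Stratification of Breast Tumours with Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic biclustering of tumour expression profiles on gene
    subsets, a resampling null for survival-curve separation, nearest
    shrunken centroid gene classifiers for bicluster pairs, and
    bicluster-augmented early-relapse prediction with conditional-inference
    trees and ridge-penalized Cox regression, evaluated by stratified
    cross-validation. Includes a synthetic-data generator that plants
    overlapping expression modules with cohort batch effects, clinical
    covariate skew and module-dependent censored survival times, so the
    whole pipeline can be exercised and tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    optparse,
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
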