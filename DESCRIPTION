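Package: rssvm
Title: Random-Survey SVM Feature Selection for Voxel-Based Morphometry
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-based feature detection for binary disease-versus-control
    classification of gray-matter-density maps. Builds per-group voxel
    summary matrices, deletes voxels with equal group values, derives
    survey-size bounds from the extrema of a pairwise voxel similarity
    statistic, and selects features by repeated random surveys scored with
    a grid-search-tuned soft-margin kernel SVM (authored SMO solver).
    Includes a seeded synthetic-cohort generator with planted informative
    voxels, four comparison classifiers (linear regression, Lasso by
    coordinate descent, PLS by NIPALS, plain SVM), confusion-matrix and
    ROC/AUC evaluation, and a repeated-split comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    quadprog,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
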