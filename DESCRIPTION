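Package: deltarad
Title: Delta-Radiomics Texture Analysis with Machine-Learning Feature
    Selection and Survival-Class Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for longitudinal (delta-) radiomics of co-registered 3D
    image volumes. Quantizes a tumor region of interest to a fixed number of
    grey levels and extracts 61 radiomic features per image (grey-level
    co-occurrence, run-length, size-zone and neighbourhood grey-tone
    difference texture families plus morphological and intensity-histogram
    features), computes relative-change delta features between imaging time
    points, screens features by univariate Cox proportional-hazards
    regression, ranks them with random-forest out-of-bag permutation
    importance, neural-network input ablation or L1-penalized logistic
    regression, and evaluates seven binary classifiers by pooled-score
    leave-one-out cross-validated ROC analysis. Includes a synthetic
    multi-timepoint two-modality cohort generator with a plantable
    post-treatment texture-change effect for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    survival,
    glmnet,
    randomForest,
    e1071,
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
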