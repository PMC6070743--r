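Package: ccradiomics
Title: Corpus Callosum Radiomics Feature Extraction and Diagnostic Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible radiomics pipeline for sagittal corpus-callosum
    regions of interest in 3D T1-weighted MR volumes. Extracts a fixed
    385-feature catalogue (first-order histogram statistics, 3D shape
    descriptors, gray-level co-occurrence and run-length texture features at
    pixel offsets 1, 4 and 7 along four in-plane angles), applies a
    three-stage feature-selection cascade (normality-routed univariate
    testing, Spearman redundancy pruning, and L1-penalised logistic
    regression with stratified cross-validation), and fits and evaluates a
    logistic diagnostic model with ROC analysis and a full confusion-matrix
    metric panel. A synthetic-cohort generator produces arch-shaped
    corpus-callosum-like masks and class-dependent in-ROI texture so the
    whole pipeline can be exercised and validated without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    jsonlite,
    ggplot2,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
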