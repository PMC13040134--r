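Package: radnex
Title: Ultrasound Radiomics Risk Models for Adnexal Masses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for ultrasound-based radiomics
    classification of adnexal masses as benign or malignant: adaptive Wiener
    despeckling and per-ROI Z-score normalization, an IBSI-style registry of 74
    intensity-statistics and texture features (GLCM, GLRLM, GLSZM), feature
    screening by Mann-Whitney U tests with Benjamini-Hochberg correction and
    Pearson redundancy pruning (with MRMR and RFE alternates), risk-model
    training over four classifier families with randomized 5-fold
    cross-validated tuning, and a full validation battery (bootstrap AUC,
    DeLong comparisons, classification metrics at clinical and Youden cutoffs,
    logistic recalibration, decision-curve analysis, SHAP-based overfitting
    scores, manufacturer PCA). Includes a synthetic cohort generator that
    emulates the statistical structure of a speckle-textured ultrasound study
    population and a reference implementation of an ADNEX-style multinomial
    risk calculator for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    png,
    xgboost,
    glmnet,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
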