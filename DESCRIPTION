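Package: timeradiomics
Title: CT Radiomics Modelling of Tumor Immune Microenvironment and
    Immunotherapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for predicting tumor-immune
    microenvironment (TIME) cell infiltration (CD3+ T, CD8+ T, CD8+ TRM)
    from CT tumor regions and transferring those predictions to an
    immunotherapy cohort to stratify response and progression-free
    survival. Provides a seeded phantom/cohort simulator, an 851-feature
    radiomic extractor (first-order, shape, GLCM, GLRLM, GLSZM, NGTDM,
    GLDM over the original image and eight undecimated wavelet
    sub-bands), ICC-based feature-robustness filtering, a selector by
    classifier model-exploration grid ranked by independent-test AUC,
    DeLong AUC comparison, and Kaplan-Meier/Cox survival stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    survival,
    MASS,
    e1071,
    kernlab,
    randomForest,
    glmnet,
    rpart,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
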