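Package: facescreen
Title: Markerless Facial-Feature Screening for Hypomimia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A classical computer-vision screening pipeline for hypomimia
    (the "masked face" of Parkinson disease) built on 2D grayscale face
    videos. Provides 68-point landmark normalization to a canonical frame
    via a closed-form similarity transform, mouth characteristic-triangle
    geometric features (corner-angle change between neutral and smile-apex
    frames, overall and per-side mouth deviation angles), HOG and uniform
    LBP texture descriptors over eye and mouth regions, SVM/KNN/random
    forest classification with stratified splitting and leakage-safe
    standardization, ROC/AUC/Youden-index evaluation, clinical-covariate
    correlation tables with Fisher-z confidence intervals, and a
    repeated-measures ANOVA power calculator. Includes a fully synthetic
    two-group face-cohort generator with analytic ground-truth landmarks so
    the entire pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    png,
    e1071,
    randomForest,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
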