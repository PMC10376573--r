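Package: octpyramid
Title: Multi-Scale Pyramidal Feature Ensembles for Cascaded Retinal OCT
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A configurable pipeline for classifying retinal optical
    coherence tomography (OCT) B-scans into NORMAL, CNV, DME and DRUSEN.
    An autoencoder scale-adaptation module trained with a combined
    pseudo-Huber and log-cosh reconstruction loss converts images of
    arbitrary size into a three-level pyramid (224/112/56); a
    densely connected convolutional backbone with configurable growth
    rate, bottlenecks and transition layers extracts a global-pooled
    feature vector per scale; the per-scale vectors are concatenated
    into a fused predictor; and a two-stage cascade (normal versus
    abnormal, then three-way disease subtyping) or an all-at-once
    four-class head performs the diagnosis with six pluggable
    classifier families. Includes a synthetic layered B-scan generator
    with speckle noise and class-specific lesions, stratified
    cross-validated evaluation (confusion matrices, accuracy,
    sensitivity, specificity, ROC/AUC) and paired t-tests for method
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    glmnet,
    rpart,
    randomForest,
    e1071,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    EBImage,
    optparse
Config/testthat/edition: 3
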