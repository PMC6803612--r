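Package: petradiomics
Title: PET/CT Radiomic Signatures for Tumor Mutation-Status Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and evaluate radiomic signatures from paired
    FDG-PET/CT tumor images for binary mutation-status prediction. Provides a
    synthetic two-class PET/CT phantom cohort generator, SUV-based isocontour
    tumor segmentation, conventional PET metrics (SUVmax, SUVmean, SUVpeak,
    MTV, TLG), a 38-feature radiomic extractor (morphology, grayscale
    statistics, gray-level co-occurrence, gray level-gradient co-occurrence,
    and gray-level difference statistics), a statistical screening battery
    (Wilcoxon rank-sum with Benjamini-Hochberg control, Spearman correlation,
    ROC analysis with a Noether test against chance), and signature
    construction via LASSO feature selection with an AdaBoost classifier under
    repeated stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    rpart,
    withr
Config/testthat/edition: 3
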