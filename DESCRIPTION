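Package: perifusion
Title: Multimodal Fusion of Radiograph Features and Clinical Records for
    Systemic Disease Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-phase multimodal pipeline for predicting systemic disease
    membership from oral health data. Phase one trains a dual-loss
    convolutional autoencoder (joint reconstruction and severity
    classification loss) on panoramic-radiograph-like images to extract
    periodontal-disease-related latent features without pixel annotation.
    Phase two fuses those latent features with eight demographic and
    clinical features in a three-branch neural classifier, one binary model
    per disease chapter. Includes a synthetic-cohort generator with planted,
    spatially localized lesion signal and a known latent risk model; a full
    evaluation harness (ROC/AUC with DeLong confidence intervals, paired
    DeLong AUC comparison, stratified splits, ten-fold cross-validation,
    class-balance downsampling, threshold metrics); and interpretability
    tools (Grad-CAM saliency over the encoder's classification path with
    quantitative lesion localization scoring, and PCA projection of the
    latent space).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    yaml,
    cluster
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
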