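Package: ceusalnm
Title: Text-Video Contrastive Learning for Predicting Axillary Lymph Node
    Metastasis from Contrast-Enhanced Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dual-branch text-video contrastive learning framework for
    classifying contrast-enhanced ultrasound (CEUS) video of breast lesions
    into axillary-lymph-node metastatic versus non-metastatic. Provides
    annotation-band removal by threshold and largest-connected-component
    cropping, keyframe-window frame sampling, a random prompt pool with a
    subword-tokenized text transformer, a patch-token video transformer with
    temporal position embeddings and an LSTM temporal head, residual feature
    adapters with a backpropagation-learned mixing coefficient, a
    bidirectional KL contrastive objective, patient-level stratified
    cross-validation, ROC and decision-curve evaluation, and a synthetic CEUS
    video generator for end-to-end testing. All neural components run on a
    self-contained reverse-mode automatic differentiation engine over base R
    matrices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    pROC,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
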