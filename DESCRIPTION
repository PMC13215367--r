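Package: lesionseg
Title: Patch-Focal Losses, Contrastive Pretraining and Lesion-Wise
    Evaluation for 3D Lesion Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A scale-configurable toolkit for detecting and delineating
    small contrast-enhancing lesions (such as brain metastases) in 3D
    scalar volumes.  Provides a seeded synthetic phantom generator for
    T1c-like volumes with ellipsoidal lesions, a hybrid
    encoder-transformer-decoder segmentation network with a built-in
    reverse-mode automatic differentiation tape, a composite training
    objective combining Dice, cross-entropy and a patch-level focal
    ("local region perceptron") term for extreme foreground-background
    imbalance, supervised contrastive (InfoNCE) pretraining of the
    encoder latent tokens, a two-stage freeze/fine-tune training
    schedule, and a lesion-wise evaluation protocol (morphological
    closing, 26-connected components, coverage matching, size-stratified
    sensitivity/precision and per-lesion Dice).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
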