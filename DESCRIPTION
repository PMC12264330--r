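Package: vesselseg
Title: Robust Vessel Wall Segmentation Training with Misaligned Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage student/mean-teacher training framework for multi-contrast
    3D vessel wall segmentation with noisy (partially misaligned) manual labels.
    Implements multi-class Dice and weighted cross-entropy losses, exponential
    moving average teacher updates, fast gradient sign method (FGSM) adversarial
    regularization, and a surrogate-label generator based on selective probability
    hardening of ensembled student/teacher predictions. Includes a synthetic
    multi-contrast vascular phantom generator with controllable partial-contour
    label misalignment, fused student/teacher sliding-window inference, and an
    evaluation suite (Dice, 95th-percentile Hausdorff distance, average surface
    distance, Tukey HSD comparisons), so the framework can be exercised end to end
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
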