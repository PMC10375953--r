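Package: stabseg
Title: Semi-Supervised Image Segmentation with Mean-Teacher Training and
    Stability-Scored Pseudo-Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised multi-class segmentation of sparsely annotated
    image volumes (CT-style slice stacks) combining Mean-Teacher consistency
    training with selective self-training. A teacher network, the exponential
    moving average of a student, provides consistency targets under input and
    dropout perturbations; after each training round, pseudo-labels on
    unlabeled slices are ranked by a checkpoint-stability score (mean IoU of
    intermediate pseudo-masks against the final one) and the most stable
    fraction is admitted into the labeled set for re-training. Includes a
    compound dice and focal supervised loss, Hounsfield-unit windowing and
    stochastic augmentation, a small parallel multi-resolution segmentation
    backbone trained by built-in backpropagation, a seeded synthetic texture
    benchmark emulating sparse slice-wise annotation, per-class dice
    evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
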