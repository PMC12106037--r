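Package: munet3d
Title: Lightweight Multi-Task 3D U-Net for Volumetric Lesion Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, profiling and training a lightweight
    multi-task mobile 3D U-Net for binary lesion segmentation in
    single-channel MRI-like volumes. The network replaces standard 3x3x3
    convolutions with 3D depthwise-separable convolutions arranged into
    channel-expansion convolution (CEC) units and inverted residual blocks,
    and optionally attaches an auxiliary lesion-present classification head
    to the encoder. The package provides exact analytic parameter and
    multiply-accumulate (FLOP) accounting for every layer, a constrained
    search that pins unprinted architecture hyperparameters to published
    complexity tables, Dice and cross-entropy losses, IoU/DSC evaluation
    metrics, a reproducible CPU training loop with cosine-annealed Adam,
    NIfTI volume I/O, and a synthetic phantom generator producing MRI-like
    volumes with ellipsoidal lesions and aligned ground-truth masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    oro.nifti,
    testthat (>= 3.0.0),
    withr,
    yaml
LinkingTo:
    Rcpp
Config/testthat/edition: 3
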