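Package: spineseg
Title: Post-Processing, Labeling and Evaluation of Vertebra Segmentations on CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream workflow for convolutional-network vertebra
    segmentations on computed tomography: refinement of binary vertebral-body
    predictions into separated instances (candidate detection by size, spine-axis
    position and inter-region distance; marker-controlled watershed splitting of
    fused vertebrae), anatomical level assignment for the thoracolumbar spine
    (T1-L5) by consensus anchoring and craniocaudal propagation via the
    sequential and combined strategies, per-vertebra evaluation (Dice, Hausdorff,
    labeling accuracy with offset-by-one attribution), a blinded contour-review
    protocol, and a seeded synthetic spine phantom generator with simulated
    network-failure corruptions for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
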