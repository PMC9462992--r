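Package: aopmeter
Title: Automatic Measurement of the Fetal Angle of Progression from
    Transperineal Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end automatic measurement of the angle of progression
    (AoP) from transperineal-ultrasound-like images. Provides a seeded
    synthetic phantom generator with analytically known ground truth, a
    multitask encoder-decoder network (standard-plane classification,
    pubic-symphysis/fetal-head segmentation, endpoint heatmap regression)
    with efficient channel attention and cross-decoder attention fusion,
    a convex shape-constrained segmentation loss, two-stage training on a
    compact reverse-mode autodiff core, ellipse-fit/tangent geometry that
    turns network outputs into an angle, and the full evaluation suite
    (classification rates, Dice, endpoint distances, axis angle, delta-AoP,
    Pearson correlation and Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
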