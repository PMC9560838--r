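Package: cathtrack
Title: Hybrid Catheter Tip Localisation in Echocardiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localising a catheter tip in 2-D echocardiography by
    combining electromagnetic (EM) pose tracking with deep-learning image
    segmentation. Provides a pivot-calibration solver that recovers the
    sensor-to-tip offset and the fixed pivot point from 6-DOF tracker logs by
    stacked least squares, a synthetic echocardiography generator that renders
    speckled sector images with a bright curvilinear catheter and paired
    ground-truth masks, a patch-based 2-D UNet segmentation pipeline trained
    with smoothed Dice loss (implemented on a compact CPU convolutional
    engine), and evaluation utilities that track the tip across frame
    sequences and report Dice accuracy and tip localisation error.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
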