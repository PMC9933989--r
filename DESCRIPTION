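Package: midlinenet
Title: Multitask Glottis Segmentation and Glottal Midline Keypoint Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous glottis segmentation and glottal midline detection for
    high-speed videoendoscopy. Implements a dual-decoder U-Net family that
    predicts a glottal-area segmentation map together with localization maps
    for the anterior and posterior points (the two anchor points defining the
    glottal midline), temporal variants (multi-frame channels, 3D convolutions,
    convolutional LSTM), moving-median temporal filtering of point
    trajectories, MAPE/IoU evaluation, a seedable synthetic endoscopy-video
    generator with ground-truth masks and points, and dataset I/O in a
    BAGLS-style layout. Networks are trained with Adam on a Dice + MSE
    multitask objective using compiled convolution kernels and reverse-mode
    automatic differentiation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
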