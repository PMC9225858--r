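Package: livercnn
Title: Patch-Based Convolutional Neural Network Segmentation of the Liver in CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Slice-wise liver segmentation of abdominal CT by per-pixel
    classification of 32x32 intensity patches with a small convolutional
    neural network (three convolution blocks with local response
    normalization, two fully connected layers, softmax). Provides a
    synthetic abdominal phantom generator with ground-truth masks,
    preprocessing and right-angle augmentation, balanced foreground /
    background patch sampling, Gaussian weight initialization, stochastic
    gradient descent with momentum under a piecewise learning-rate
    schedule, sliding-window probability-map inference with median-filter
    post-processing, and an eight-metric evaluation suite (sensitivity,
    specificity, accuracy, precision, FPR, FNR, Jaccard, Dice). The
    network forward and backward passes are implemented in C++ via
    RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
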