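Package: hipposeg
Title: Two-Stage Atlas-Guided Hippocampus Segmentation for T1-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic segmentation of the left and right hippocampus from
    3D T1-weighted MRI volumes using a two-stage pipeline: an atlas
    registration step localises a region of interest around each
    hippocampus, and a 3D patch-based fully-convolutional neural network
    classifies every voxel inside the dilated atlas mask as hippocampus or
    background. Includes volume preprocessing (z-score intensity
    standardisation, isotropic resampling), affine, rigid and non-linear
    image registration driven by cross-correlation, morphological
    region-of-interest extraction, network training with class-balanced
    patch sampling and Gaussian-blur augmentation, Dice and
    volume-difference evaluation, a test-retest precision protocol, and a
    synthetic brain-phantom generator with ground-truth labels for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
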