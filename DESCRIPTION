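Package: adiposeg
Title: Abdominal Adipose Tissue Segmentation and Quantification from
    T1-Weighted MRI Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for discriminating and quantifying
    abdominal subcutaneous (SAT) and visceral (VAT) adipose tissue in
    T1-weighted MRI: multi-station volume registration and merging,
    supersampling to isotropic voxels, median filtering, an
    intensity-range/connectivity reference segmentation, an
    encoder-decoder convolutional network (U-Net) for three-class
    pixelwise segmentation trained with categorical cross-entropy and
    adaptive moment estimation, Dice and pixel-error evaluation,
    volumetric fat quantification with VAT/SAT ratio group statistics,
    and a seeded synthetic abdominal phantom generator with ground-truth
    masks for validation when patient data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    png,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'adiposeg-package.R'
    'io-formats.R'
    'metrics.R'
    'phantom.R'
    'quantify-stats.R'
    'unet.R'
    'preprocess.R'
    'reference-seg.R'
    'pipeline.R'
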