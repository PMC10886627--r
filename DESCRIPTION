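Package: ramanhisto
Title: Tissue Classification for Stimulated Raman Scattering and Raman
    Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for patch-based tissue classification
    on two-channel stimulated Raman scattering (SRS) microscopy images and
    their virtual-H&E (stimulated Raman histology, SRH) renderings.
    Provides a synthetic specimen generator with per-class Raman texture
    signatures and QuPath-dialect GeoJSON annotations, three-channel tensor
    construction (CH2, CH3, CH3-CH2), annotation-driven grid tiling under a
    99 percent coverage rule, Jensen-Shannon-distance stratified
    image-level train/validation/test splitting, a class-weighted
    convolutional neural network classifier, and a per-class
    precision/recall/F1/balanced-accuracy evaluation suite with confusion
    matrix reports.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'ramanhisto-package.R'
    'utils.R'
    'tissue_classes.R'
    'srs_image.R'
    'annotation.R'
    'tiling.R'
    'splitting.R'
    'classifier.R'
    'evaluation.R'
    'synthetic_data.R'
    'pipeline.R'
    'reference.R'
    'RcppExports.R'
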