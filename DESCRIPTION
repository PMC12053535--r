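Package: GTVseg
Title: Patch-Based 3D U-Net Segmentation of Gross Tumor Volumes on MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pure-R toolkit for patch-based three-dimensional semantic
    segmentation of primary gross tumor volumes (GTVp) and metastatic lymph
    nodes (GTVn) on T2-weighted MRI. Implements a configurable six-stage 3D
    U-Net with per-stage kernel control, patch-wise z-score intensity
    normalization, a scheduled data-augmentation policy, Gaussian-weighted
    sliding-window inference, the aggregated Dice similarity coefficient
    (DSCagg) and the present-class batch Dice loss, together with NIfTI
    volume I/O, resampling, synthetic MRI phantom generation and a
    desk-scale training workbench with Adam optimization and cosine
    learning-rate decay.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    Rcpp,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
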