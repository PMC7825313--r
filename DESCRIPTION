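Package: tmdunet
Title: Triple U-Nets with Multi-Scale Inputs and Dense Skip Connections for
    Medical Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains the triple U-Net family of encoder-decoder
    segmentation networks (T-Unet and TMD-Unet) in which every resolution
    level holds three densely connected dilated-convolution units forming
    three parallel sub-networks, optionally augmented with a multi-scale
    input pyramid and dense skip connections. Includes a small static-graph
    engine with exact trainable-parameter accounting per sub-network output,
    hybrid dice plus (weighted) cross-entropy losses, overlap and
    confusion-matrix evaluation metrics, the dataset-preparation operators
    used for 2-D medical images and CT/MRI volumes (sliding-window tiling,
    intensity windowing, cropping, resizing, adjacent-slice stacking,
    empty-slice decimation), a deterministic synthetic blob generator, a
    CPU training harness with Adam, exponential learning-rate decay and
    paired image/mask augmentation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    png,
    tiff,
    yaml,
    jsonlite,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
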