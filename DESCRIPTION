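Package: countnet
Title: Count-Supervised Counting Networks for Dense Field Objects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds, trains and inspects count-supervised counting
    networks for dense small objects in field images, such as wheat
    ears and grains.  The model couples a truncated VGG-style
    convolutional backbone with channel and spatial attention (CBAM),
    a multiscale patch-slicing perception stage built from MLP-mixer
    layers, and a direct count-regression head, so it learns from
    per-image totals alone - no bounding boxes or density maps.
    Includes a seeded synthetic field-image generator with exact count
    labels, loaders for count manifests and box-annotation tables,
    counting metrics (MAE, RMSE, R squared) with density-stratified
    reports, and gradient-weighted attention heatmaps for regression
    models.  All network arithmetic, including backpropagation, is
    implemented in the package with small compiled kernels for the
    convolution and pooling primitives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: png, stats, grDevices, graphics, utils, tools, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
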