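Package: mrisr
Title: Residual-Learning Super-Resolution for 2D Brain MRI Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-image super-resolution for 2D brain MRI slices using a
    residual-learning convolutional network with transposed-convolution
    upsampling, trained with a combined Charbonnier and gradient-difference
    loss. Includes the bicubic degradation model used to derive paired
    low/high-resolution data, classical interpolation baselines (cubic
    spline, non-local-means upsampling), PSNR/SSIM evaluation with
    mean/SD/confidence-interval reporting, a synthetic brain-phantom
    generator so the full pipeline runs without external data, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    RNifti,
    png,
    tiff,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
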