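Package: se2recon
Title: SE(2) Group-Wavelet Image Analysis and Reconstruction from
    Orientation-Preference Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete SE(2) group-wavelet analysis of square grayscale
    images with Gabor receptive-field filter banks, modelled on the
    orientation-selective simple cells of the primary visual cortex.
    Provides the forward and adjoint transforms, Calderon admissibility
    diagnostics with frame bounds, dual filters for exact inversion on
    bandlimited images, the orthogonal projection onto the reproducing
    kernel subspace spanned by the transform, and a project-and-replace
    iteration that reconstructs an image from transform values retained
    only on a cortical-style feature map (uniformly random, pinwheel, or
    constant orientation-preference maps). A dense-matrix solvability
    oracle certifies uniqueness of the restricted reconstruction problem
    and its contraction rate on small instances, and a phantom generator
    produces 8-bit test images with natural-image-like power-law spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    png,
    tiff,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
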