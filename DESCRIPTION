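Package: nmaflex
Title: Normal-Mode Based Analysis of Continuous Conformational
    Heterogeneity in Cryo-EM Single-Particle Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A hybrid pipeline for analysing continuous conformational
    heterogeneity in cryo-EM single-particle images.  Elastic-network
    normal mode analysis (with rotation-translation-block acceleration)
    supplies collective motion directions for a reference structure; a
    ground-truth simulator synthesises particle images along a
    parametric conformational trajectory with projection, contrast
    transfer function, two-stage noise and antialiased downscaling; an
    iterative elastic plus rigid-body 3D-to-2D aligner and a residual
    convolutional network regressor estimate per-image normal-mode
    amplitudes, orientations (quaternions) and in-plane shifts; and
    downstream tools build a PCA conformational space, filter outliers
    by Mahalanobis distance, reconstruct 3D maps by direct Fourier
    inversion and report Fourier shell correlation and per-parameter
    error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    grDevices,
    graphics,
    bio3d,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
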