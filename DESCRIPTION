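Package: sinomar
Title: Sinogram-Domain Metal Artifact Reduction for CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Metal artifact reduction (MAR) for computed tomography carried
    out in the sinogram domain. Simulates paired complete and metal-damaged
    parallel-beam sinograms from random ellipse phantoms, completes the
    damaged metal traces with a compact convolutional encoder-decoder
    network trained under a masked L2 loss augmented with a detector-axis
    continuity penalty and a Helgason-Ludwig consistency penalty,
    reconstructs images by filtered back projection, and evaluates
    completion quality against a one-dimensional linear-interpolation
    baseline using MAE, RMSE and NMAD metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
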