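Package: cspat
Title: Compressed-Sensing Measurement Design and Two-Step Reconstruction for
    Circular Photoacoustic Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing structured binary compressed-sensing
    measurement matrices for circular-array photoacoustic projection imaging
    and for reconstructing images from the compressed data. Measurement rows
    activate at most one sensor per hardware switch block; candidate matrices
    are scored by the s-sparse injectivity number (the minimum smallest
    singular value over all 2s-column submatrices) and optimized by random
    search. A 2D circular-geometry forward model (closed-form circular means
    of disk phantoms composed with an Abel-type time transform) and a
    filtered-backprojection inversion support end-to-end experiments: total
    variation regularized recovery of the transformed detector data from
    compressed measurements followed by filtered backprojection, with
    synthetic phantoms, calibrated noise injection, and relative-error
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    jsonlite,
    png,
    tools,
    pracma,
    Rcpp,
    generics,
    optparse,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
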