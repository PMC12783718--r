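Package: cladescan
Title: Explainable Image Classification and Outline Morphometrics for
    Cryptic Clade Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects subtle (cryptic) morphological divergence between
    genetically defined clades from standardized specimen images. Provides a
    synthetic shell-image generator with plantable clade effects (keyhole
    narrowing and pinching, ridge irregularity, banding, overlapping size
    distributions), a seeded resampling protocol with a mixed-group
    randomized-label control, a small convolutional classifier trained from
    scratch with macro-F1 evaluation, SmoothGrad saliency maps with
    region-attention enrichment, mask-based shape descriptors (circularity,
    eccentricity, solidity, extent, minor-axis length), Karcher-mean outline
    averaging with six-landmark width analysis, and nonparametric comparison
    and reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    grDevices,
    utils,
    png,
    EBImage,
    jsonlite,
    tibble,
    dplyr,
    ggplot2,
    readr,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
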