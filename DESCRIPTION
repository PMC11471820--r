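Package: cystinetics
Title: Kinetic Analysis of Disulfide Photolysis from Transient X-Ray Absorption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models the ultrafast UV photochemistry of aqueous L-cystine as a
    branching sequential rate-equation system (excited parent, thiyl and
    perthiyl radicals, vibrationally excited recombination intermediate),
    solves the populations analytically with Gaussian instrument-response
    convolution, and fits the shared kinetic parameters globally to
    multi-channel sulfur K-edge transient-absorption delay scans by weighted
    nonlinear least squares. Includes a synthetic-experiment generator with
    shot-level noise, residual-bootstrap and simulation-based uncertainty
    tools, and utilities to compose and decompose static and differential
    XANES spectra from pseudo-Voigt line lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    yaml,
    jsonlite,
    stats,
    utils,
    pracma,
    minpack.lm,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
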