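Package: afsmcr
Title: Area of Feasible Solutions Analysis for Multivariate Curve Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: SVD-based multivariate curve resolution (MCR) for spectroscopic
    series, with an explicit treatment of rotational ambiguity. Computes the
    area of feasible solutions (AFS) for the spectral and the concentrational
    factor of a bilinear model D = C S' (closed form for two-component
    systems, adaptive boundary tracing for three-component systems), reduces
    the ambiguity via the duality/complementarity between the two factors
    when pure spectra or concentration profiles are known, represents the
    remaining ambiguity as bands of feasible profiles, applies closure
    (mass-balance) scaling, and validates decompositions by rank-annihilation
    and by hard-modeling of the titration kinetics. Includes a ground-truthed
    synthetic acid-base titration generator so the whole workflow is testable
    without measured data, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
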