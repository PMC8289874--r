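Package: ejectr
Title: Kinetics of Polymer Ejection from a Quasi-Two-Dimensional Cavity
    Through a Nanopore
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the spontaneous ejection of a confined polymer
    through a nanopore channel. Provides a coarse-grained bead-spring
    Langevin dynamics engine for a disk-like cavity embedded in a slit
    (quasi-two-dimensional geometry), a d-dimensional scaling theory of the
    ejection kinetics (free-energy landscape, Onsager kinetics, Kramers
    first-passage times, stage-time predictions), an analysis pipeline for
    ejection event series (waiting-time function, ejection speed, stage
    decomposition, critical-size detection, scaling-exponent fits), and a
    synthetic event-series generator so the analysis layer is testable
    without running molecular dynamics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
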