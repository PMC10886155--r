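Package: okfea
Title: Patient-Specific Finite Element Simulation of Orthokeratology Lens Wear
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling overnight orthokeratology (Ortho-K) contact
    lens wear on patient-specific anterior eye models. Reads polar corneal
    topography elevation grids, computes tangential power and refractive power
    change (RPC) maps with robust discretized-spline smoothing, detects the
    central flattened and annular steepened treatment zones and lens
    decentration, reconstructs eyelid geometry from topography coverage
    footprints, builds hexahedral meshes of the cornea, reverse-geometry lens
    and eyelid, seats the lens by constrained iterative closest point
    registration, runs a staged implicit finite-element contact simulation
    (stress-free geometry recovery, IOP inflation, lid settle, tear traction,
    lid closure), and compares the resulting stress/strain barometer fields
    against RPC maps via 2D normalized cross-correlation and the structural
    similarity index. A seeded synthetic-data generator emulates a clinical
    topography cohort so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    rlang,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
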