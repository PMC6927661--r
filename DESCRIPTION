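Package: cpmforce
Title: Cell Shape Simulation and Force Inference with the Cellular Potts Model
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates single and multicellular systems with the
    two-dimensional Cellular Potts Model (area, perimeter and adhesion
    energies evolved by Metropolis dynamics under a connectivity
    constraint) and computes the traction-force field consistent with the
    model energy: centered finite differences of the Hamiltonian at the
    cell boundary, perimeter-weighted smoothing against lattice
    artifacts, and centroid-ray interpolation into the cell interior.
    Includes a wave-pinning reaction-diffusion polarization module
    coupled to the lattice dynamics, scenario fixtures (shrinking cells,
    adhering pairs, cell sorting), force-field comparison metrics, a
    synthetic reference-field generator, and Latin hypercube parameter
    search.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
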