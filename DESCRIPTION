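Package: pelwater
Title: Potential Energy Landscape Analysis of Quantum Water by Path-Integral
    Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the potential-energy-landscape (PEL) formalism for a
    quantum molecular liquid, exercised on the flexible q-TIP4P/F water model.
    Provides the q-TIP4P/F potential with analytic forces and mass-weighted
    Hessians (open clusters and periodic boxes with reaction-field
    electrostatics), a path-integral molecular dynamics engine with the
    path-integral Langevin equation (PILE) thermostat and a Monte Carlo
    barostat, inherent-structure minimization of both the classical and the
    ring-polymer landscape, the analytic ring-polymer normal-mode spectrum at
    collapsed inherent structures together with its brute-force Hessian
    oracle, and the Gaussian/harmonic landscape statistics layer (basin shape
    function, configurational entropy, vibrational and Helmholtz free
    energies). Desk-scale protocols cover constant-volume state-point scans,
    toy isobaric vitrification, and structural analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
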