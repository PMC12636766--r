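Package: critppi
Title: Lattice Monte Carlo Simulation of Protein Interaction Networks in
    Near-Critical Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates protein-protein interaction (PPI) networks embedded in
    a lipid membrane poised near its liquid-liquid miscibility critical point.
    The membrane is a conserved-order-parameter (Kawasaki) Ising lattice;
    proteins are disk-shaped inclusions whose boundaries couple to adjacent
    lipid spins and that diffuse by detailed-balance translation moves.
    Contact reactions change inclusion states (and optionally their domain
    partitioning) at fixed rates, making the activity dynamics a driven,
    non-equilibrium process on an otherwise equilibrium solvent. Includes a
    diagrammatic sign-product predictor for the temperature response of a
    network, steady-state activity analysis, generalized logistic (tanh)
    response-curve fitting with confidence intervals, radially averaged
    cross-correlation functions, detectors for kinetically trapped "pocket"
    domains, and an exhaustive Boltzmann enumeration oracle for validating
    the samplers on tiny systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tibble,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
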