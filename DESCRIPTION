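Package: excitube
Title: Exciton Dynamics and Polarization-Resolved 2D Electronic
    Spectroscopy of Cylindrical Molecular Aggregates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds helical cylindrical aggregates of coupled chromophores
    (chlorosome-like J-aggregates) by rolling a two-dimensional dipole
    lattice at a chiral angle, drives the site energies with stationary
    colored-noise bath trajectories, and propagates the time-dependent
    Frenkel exciton Hamiltonian by numerical integration of the
    Schroedinger equation in the high-temperature limit.  From the
    propagated wavefunctions the package computes linear absorption,
    linear dichroism and its parallel/perpendicular decomposition,
    polarization-resolved absorptive two-dimensional electronic spectra
    (ground-state bleach, stimulated emission and excited-state
    absorption pathways, rephasing and nonrephasing), and ultrafast
    transient-absorption anisotropy decay traces with exponential fits.
    The helicity of the cylinder, summarized by the distribution of
    angles between the molecular transition dipoles and the cylinder
    axis, controls the presence or absence of sub-picosecond anisotropy
    decay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
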