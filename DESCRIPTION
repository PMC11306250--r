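Package: myotrap
Title: Single-Molecule Optical-Trap Mechanics and Transient Kinetics for
    Myosin Motors
Version: 0.1.0
Authors@R:
    person("Myotrap", "Developers", email = "myotrap@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for three-bead optical-tweezers assays of
    single myosin motors and for stopped-flow solution kinetics, built around
    the chemo-mechanical ATPase cycle of myosin VI (MYO6) and its S267
    phospho-mutants. Provides a closed-form crossbridge cycle model with
    Bell-type load-dependent rates, an exact stochastic simulator of the
    two-bead actin-dumbbell network (Markov state sequences, overdamped
    Langevin bead traces with sinusoidal forcing, stopped-flow transients),
    variance-threshold binding-event detection, cumulative dwell-time
    double-exponential fits, Gaussian working-stroke fits, start/end
    synchronised ensemble averaging of displacement and of demodulated
    crossbridge stiffness, Bell-equation load fits, and single-exponential
    transient fits with second-order rate titrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
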