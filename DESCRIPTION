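Package: psdkin
Title: Kinetic Modelling and Parameter Estimation for the Photo-Sensitive Degron Module
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and parameter estimation for the blue-light controlled
    photo-sensitive degron (psd) module, an engineered fusion of the Arabidopsis
    phototropin1 LOV2 domain with a synthetic ornithine-decarboxylase degron.
    Implements the two-state (dark/lit) photoreceptor kinetic model with
    endogenous and degron-mediated proteasomal degradation, deterministic ODE
    and exact stochastic (Gillespie) simulation of cycloheximide-chase
    experiments, first-order exponential-decay half-life fitting, and a
    multi-experiment parameter estimator based on multiple shooting and a
    constrained generalized Gauss-Newton method with prior regularization and
    linearized standard errors. Includes a synthetic chase-data generator and
    a catalog of characterized psd module variants for end-to-end recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
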