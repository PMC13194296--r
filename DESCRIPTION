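Package: oncoctrl
Title: Ensemble Optimal Control of Adaptive Cancer Therapy Schedules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and optimization of drug-dosing schedules for tumors
    composed of drug-sensitive and drug-resistant subpopulations competing under
    a Lotka-Volterra model. Provides the non-dimensional two-population model and
    its n-species control-affine generalization, feedback therapy protocols
    (maximum tolerated dose and threshold-based adaptive therapy), time-to-
    progression metrics over parameter ensembles, integral tumor-burden costs
    (linear and hyperbolic), and ensemble optimal control by projected gradient
    descent with exact discrete-adjoint gradients, in both ensemble-averaged and
    worst-case (minimax) formulations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    withr,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
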