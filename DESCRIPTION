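Package: piptazpk
Title: Population Pharmacokinetics and Dosing Simulation for
    Piperacillin/Tazobactam
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-compartment population pharmacokinetic models of
    piperacillin and tazobactam with renal-function covariates, an exact
    analytic solver for piecewise zero-order infusion schedules including
    steady state, Monte Carlo simulation of virtual patient cohorts
    stratified by renal function, probability of target attainment (PTA)
    for %fT>MIC pharmacodynamic targets, PK/PD breakpoints and cumulative
    fraction of response (CFR), and nonlinear mixed-effects estimation by
    Laplace approximation with covariate stepping, bootstrap, visual
    predictive checks and goodness-of-fit diagnostics. A synthetic-study
    generator reproduces the single-dose rich-sampling design in healthy
    adults so that the entire workflow can be exercised without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
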