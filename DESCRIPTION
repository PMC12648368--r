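Package: atvrpk
Title: Population Pharmacokinetics of Ritonavir-Boosted Atazanavir with
    Rifampicin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects pharmacokinetic modelling of
    ritonavir-boosted atazanavir given alone and with rifampicin: a
    transit-compartment absorption, two-compartment disposition model with
    an effect-compartment link to intracellular (PBMC) concentrations;
    log-normal between-subject, between-visit and between-occasion
    variability with combined residual error and below-quantification-limit
    handling; Laplace (FOCE-like) marginal-likelihood estimation with
    likelihood-ratio covariate testing and sampling-importance-resampling
    uncertainty; Monte Carlo simulation of steady-state trough
    concentrations and probability of target attainment; visual predictive
    checks; and a synthetic-data generator emulating a four-visit
    rifampicin dose-escalation interaction study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils,
    withr,
    yaml,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
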