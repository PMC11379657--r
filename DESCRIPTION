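Package: tvclpk
Title: Population Pharmacokinetics with Time-Varying Clearance for
    Subcutaneous Antibody Therapeutics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of subcutaneously
    administered therapeutic antibodies whose apparent clearance changes with
    treatment time. Implements a one-compartment model with first-order
    absorption and an Emax-type time-dependent elimination term, covariate
    models on clearance and volume (renal function, country, body weight),
    nonlinear mixed-effects estimation (Laplace and FOCE-style approximate
    marginal likelihood) with empirical-Bayes individual estimates, stepwise
    covariate selection, nonparametric bootstrap, goodness-of-fit diagnostics
    (conditional weighted residuals, dose-corrected visual predictive checks),
    dosing-regimen simulation with steady-state exposure metrics and
    accumulation ratios, and an exposure-response stage (quartile summaries,
    logistic regression, Kaplan-Meier estimation of response duration, and
    adverse-event-of-clinical-interest filtering). A synthetic-trial generator
    reproduces the sampling designs, covariate distributions, and outcome
    structure typical of mixed phase I/II oncology PK programs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
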