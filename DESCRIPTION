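Package: clozapk
Title: Population Pharmacokinetics and Dose Individualization of Clozapine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for population-pharmacokinetic (PPK) analysis of clozapine
    in schizophrenia patients treated alongside common co-medications. Provides
    a one-compartment oral-absorption structural model with allometric body
    weight scaling and a zopiclone drug-drug interaction covariate on apparent
    clearance; a synthetic trough-sampled cohort generator; a nonlinear
    mixed-effects estimation engine (Laplace approximation with interaction,
    empirical-Bayes estimates, standard errors, stepwise covariate search);
    model qualification via goodness-of-fit records, visual predictive checks
    and nonparametric bootstrap; and Monte Carlo dose-individualization that
    converts simulated steady-state troughs into weight-banded dosing
    recommendations with toxicity-exceedance bounds.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
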