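Package: qaopcal
Title: Hierarchical Calibration of Chemical-Agnostic Quantitative Adverse
    Outcome Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits flat and hierarchical Bayesian dose to key-event to
    adverse-outcome (qAOP) models to summarized multi-chemical toxicology
    data. The upstream key event is modeled as a lognormal continuous
    endpoint driven by a continuous Hill dose-response curve; the
    downstream key event as a binomial endpoint driven by a dichotomous
    Hill response-response curve whose parameters may carry
    chemical-specific random effects. Models are fitted by a built-in
    No-U-Turn Hamiltonian Monte Carlo sampler, compared by PSIS-LOO and
    WAIC to diagnose cross-chemical heterogeneity, and used to derive
    benchmark levels (BML, BMLL, BMLU) of the upstream key event as points
    of departure. Includes a simulator that generates multi-chemical
    datasets at controlled Cohen's f heterogeneity levels and a
    flat-versus-hierarchical simulation study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
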