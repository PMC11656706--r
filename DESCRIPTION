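Package: gutspulse
Title: GUTS-RNA-Pulse Toxicokinetic-Toxicodynamic Models with Gene-Expression Damage Proxies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the GUTS-RNA-pulse family of toxicokinetic-toxicodynamic
    (TKTD) models for zebrafish embryo toxicity data: ordinary differential
    equations linking external toxicant concentration to internal concentration,
    threshold-activated nrf2 gene-expression pulses, a protein-mediated
    metabolization feedback, and stochastic-death survival. Provides log-normal
    and conditional-binomial error models, a joint likelihood over fragmented
    multi-endpoint observations, Bayesian multi-start inference with
    substance-specific or shared parameters, credible-interval trajectory
    envelopes, posterior-cluster identifiability diagnostics, model comparison
    by the Bayesian information criterion, and a synthetic-data generator that
    emulates the unbalanced multi-endpoint study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
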