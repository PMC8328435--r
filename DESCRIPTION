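Package: eiderIPM
Title: Integrated Population Model for Spectacled Eider Demography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a Bayesian integrated population model (IPM) for the
    Yukon-Kuskokwim Delta breeding population of spectacled eiders
    (Somateria fischeri), combining a state-space likelihood for aerial
    breeding-abundance estimates, a multistate Cormack-Jolly-Seber
    capture-recapture likelihood with unobservable pre-recruit states
    (m-array multinomial formulation), and binomial/Poisson productivity
    likelihoods.  Demographic rates vary by year through logit-scale
    random effects and standardized environmental covariates (quadratic
    winter sea-ice severity, Arctic Oscillation, fox sign, precipitation).
    Includes a stage-structured projection core, posterior-predictive
    goodness-of-fit checks, derived growth-rate statistics, and a
    synthetic-data generator for end-to-end testing and parameter-recovery
    studies.  MCMC sampling is performed with JAGS via rjags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
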