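Package: dualscreen
Title: Two-Stage Bayesian Estimation for Two Dependent Screening Tests
    with Unverified Double Negatives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates disease prevalence and the accuracy (sensitivity and
    specificity) of two conditionally dependent dichotomous screening tests
    when disease status is verified by a gold standard only for subjects
    positive on at least one test, so that double negatives are never
    verified.  Implements a two-stage Bayesian multinomial model with a
    covariance parameterization of the conditional dependence, two-step
    hierarchical uniform priors on the sensitivities, adaptive
    Metropolis-within-Gibbs posterior sampling, joint-testing summaries
    (joint sensitivity, joint specificity, positive predictive value), a
    four-criterion model-checking battery (pD, DIC, a local chi-squared
    posterior-predictive test, cell-wise predictive intervals and a PPV
    coverage check), and a simulator for the two-stage screening design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
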