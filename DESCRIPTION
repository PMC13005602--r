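Package: survtransport
Title: Transporting Randomized Trial Survival Results to External Target
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Inverse-probability-weighted and doubly robust estimation of
    counterfactual survival functions and the target average survival
    treatment effect (TASTE) when transporting randomized-trial results
    with right-censored outcomes to an external target population observed
    through a complex survey. Implements Horvitz-Thompson (IPW1) and Hajek
    (IPW2) style inverse-odds-of-sampling weighted estimators with inverse
    probability of censoring weighting, outcome-regression and augmented
    doubly robust estimators (DR1, DR2) with survey-weight placement rules,
    approximate influence-function variance estimators, covariate balance
    diagnostics, a data-generating simulator, and a Monte Carlo harness
    summarizing bias, empirical and average standard errors, and coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
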