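Package: emulsurv
Title: Target-Trial Emulation with Neural Propensity Scores and Weighted Deep Survival Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for emulating a randomized trial of two surgical treatments
    from inpatient-claims records and analysing it with a deep-learning
    counterpart of the propensity-score + inverse-probability-of-treatment
    (IPT) weighted Cox workflow. Provides a synthetic claims generator with
    known ground truth, claims-to-cohort assembly (eligibility filters,
    treatment-date imputation, outcome derivation, descriptive tables),
    neural-network propensity estimation with IPT weighting and balance
    diagnostics, an IPT-weighted multi-layer survival network trained on a
    weighted Cox partial-likelihood loss with Breslow baseline hazards and
    counterfactual marginal survival curves, layer-accumulated effect weights,
    a weighted Cox regression comparator with a proportional-hazards
    diagnostic, and 0.632 subsample bootstrap inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
    optparse,
    readr,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
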