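Package: copdhia
Title: Health Impact Assessment of Tobacco Price Increases on COPD Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dynamic Markov multi-state simulator projecting smoking
    behaviour (never/current/former) and chronic obstructive pulmonary
    disease (COPD) burden over a multi-decade horizon under one-time
    tobacco-price-increase scenarios. Price elasticities of demand shift
    baseline smoking-state prevalences and the annual probabilities of
    smoking initiation, cessation and restart; state-specific COPD
    incidence and mortality are obtained by attributable-risk
    decomposition of population rates with relative risks of smoking.
    Outputs include smoking prevalence trajectories, COPD prevalence and
    incidence series, cumulative incident cases saved, cohort life
    expectancies (overall, COPD-free and COPD-disability-adjusted) and
    cost savings. A synthetic-data generator produces reproducible
    country-like input bundles so the full pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
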