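Package: prscea
Title: Health-Economic Modeling of Polygenic Risk Score Guided
    Coronary Artery Disease Prevention in Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic toolkit for evaluating polygenic risk score
    (PRS) guided primordial prevention of coronary artery disease (CAD)
    starting in childhood. Provides a four-state annual-cycle Markov cohort
    engine with PRS risk strata and intervention arms, a deterministic
    societal cost-benefit ledger (events prevented, healthcare and
    productivity savings, QALY valuation, screening stratification savings,
    co-benefits, ROI and ICER), a seeded Monte Carlo probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves and
    net monetary benefit, and country-level localization of ICER and ROI
    through cost and benefit scaling factors. All model inputs are carried
    in a typed parameter registry with per-parameter probability
    distributions and a strict round-tripping YAML configuration format.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
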