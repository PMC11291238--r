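Package: psmcea
Title: Partitioned-Survival Cohort Modelling for Cost-Effectiveness Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for trial-based cost-effectiveness analysis when only
    published Kaplan-Meier curves are available: reconstruction of
    pseudo-individual patient data from digitized survival curves and
    number-at-risk tables (the Guyot algorithm), maximum-likelihood fitting
    of seven parametric survival families with AIC/BIC model selection, a
    three-state (progression-free, progressed, dead) partitioned-survival
    cohort model with discounted cost and QALY accumulation, and
    deterministic (tornado) plus probabilistic (second-order Monte Carlo,
    CEAC) sensitivity analysis. Ships a reference configuration for a
    second-line immunotherapy versus chemotherapy comparison in advanced
    non-small-cell lung cancer, and a synthetic-data generator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
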