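Package: drugsynergy
Title: Drug Combination Synergy Scoring and Mechanism-of-Synergy Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing drug-combination experiments in cancer cell
    models: four-parameter log-logistic dose-response fitting with outlier
    handling and IC50 extraction, checkerboard synergy scoring under the
    Bliss, ZIP and Loewe reference models, a reduced-dose Bliss statistic
    for two- and three-drug combinations tested at IC50/k, and the
    proteomic mechanism-of-synergy workflow (left-censored imputation,
    moderated combination-versus-sum-of-singles contrasts, SAM-style
    permutation tests and pre-ranked kinase-substrate enrichment).
    Includes a seeded synthetic-data generator that emulates the full
    study design so every stage is testable without raw instrument data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    limma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
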