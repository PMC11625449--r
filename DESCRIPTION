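Package: fatexchange
Title: Food-Exchange Modelling of Dietary Fat Intakes in Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scenario modelling of dietary fat intakes from
    multi-day food diaries. Computes per-participant mean daily intakes of
    energy, total fat and its constituent fatty acids (grams per day,
    percentage of total energy, and milligrams per day for long-chain
    omega-3s), analyses the food-category determinants of saturated-fat
    intake by consumer tertile (one-way ANOVA with Scheffe post hoc
    groupings), applies rule-driven gram-preserving exchanges of high
    saturated-fat foods for lower saturated-fat or higher unsaturated-fat
    alternatives, and quantifies the resulting change in the dietary fat
    profile and in compliance with dietary fat recommendations. Includes a
    seeded synthetic cohort generator calibrated to a target population mean
    saturated-fat intake for method development and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
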