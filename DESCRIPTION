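Package: bimpact
Title: Deterministic Budget Impact Modelling for Formulary Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for deterministic budget impact analysis (BIA) of
    adopting a new treatment within a fixed payer population: cohort
    projection under a net prevalence growth rate, market-share uptake
    scenarios, per-year and cumulative incremental budget impact,
    affordability classification against a GDP-multiple threshold, and
    one-way sensitivity analysis with spider-plot data export. Ships
    ready-to-run model fixtures for a five-year CDK4/6-inhibitor analysis
    in HR+/HER2- advanced breast cancer, with unit costs back-derived from
    the published scenario tables, plus a synthetic-model generator with
    analytically known results for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
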