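Package: healtheil
Title: Equality Analysis of Public Health Resource Allocation with the Theil Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the regional allocation of public health
    resources (institutions, technical personnel, beds, equipment) across
    Chinese provinces. Provides per-capita (per 10,000 persons) and per-area
    (per square kilometre) density indicators, percent-change trend summaries,
    and the population-weighted Theil index (mean-log-deviation form) with an
    exact within/between-region decomposition and contribution rates. Includes
    validated CSV panel ingestion with the standard western/middle/eastern
    partition of the 31 mainland provinces, packaged national and provincial
    reference tables, a seeded log-normal synthetic panel generator for
    testing the full pipeline, and a one-shot report runner with tidy series
    suitable for plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
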