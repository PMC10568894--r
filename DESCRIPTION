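Package: mhconsult
Title: Observed Versus Forecast Weekly GP Consultation Counts for Mental
    Health Problems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for registry-based surveillance of weekly general
    practitioner (GP) consultation counts for common mental health
    problems among adults with pre-existing mental health problems.
    Builds pre-pandemic and pandemic analysis cohorts from
    consultation-level extracts (ICPC-2 coded), aggregates consultations
    on an ISO-week grid, forecasts pandemic-period weekly counts by
    scaling the inclusion-year series with bootstrap-estimated mean
    Pearson correlations between pre-pandemic years, compares observed
    and forecast series with loess smoothing and 99.9% pointwise
    confidence bands, and summarises excess or deficit with a
    mean-deviation percentage. Includes a synthetic registry generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
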