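Package: hurdlecohort
Title: Matched-Cohort Healthcare Utilisation and Cost Analysis with Two-Part Hurdle Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for matched-cohort studies of healthcare
    utilisation and cost built from electronic-health-record style event
    streams. Provides a synthetic cohort generator with known ground-truth
    effects, eligibility filtering and 1:5 exact matching with seeded
    tie-breaking, person-period outcome construction with same-day
    deduplication and unit-cost assembly, two-part (hurdle) models combining
    a binomial first part with zero-truncated negative binomial or Poisson
    count parts and Gamma cost parts (all with person-time offsets),
    marginal standardised predictions with cluster bootstrap intervals,
    a two-part difference-in-differences historical comparison, and
    Table-1 descriptives with stratified and restricted sensitivity
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
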