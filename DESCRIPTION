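Package: akialert
Title: Paediatric Acute Kidney Injury E-Alert Staging and Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a creatinine-ratio acute kidney injury (AKI) e-alert
    algorithm for paediatric hospital laboratory data: each creatinine
    measurement is staged against a baseline defined as the lowest value in
    the preceding 12 months or, when no prior measurement exists, the
    age-specific upper reference limit. Provides per-patient and cohort
    incidence summaries (stage mix, age-band and per-centre distributions),
    the comparison statistics used in AKI incidence audits (chi-squared,
    Mann-Whitney U, two-sample t), a seeded synthetic cohort generator with
    known ground truth for validating the pipeline, and command-line entry
    points for running the pipeline on hospital CSV extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    rlang,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
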