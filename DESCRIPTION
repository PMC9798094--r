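Package: pvsignal
Title: Pharmacovigilance Signal Detection for Spontaneous Reporting Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for disproportionality-based signal detection in
    FAERS-style spontaneous adverse event reporting data. Reads quarterly
    $-delimited ASCII tables (DEMO, DRUG, REAC, OUTC, THER, INDI),
    deduplicates cases on (caseid, fda_dt), applies quality filters,
    normalizes drug names against a synonym dictionary and maps reaction
    preferred terms (PTs) to system organ classes (SOCs) and important
    medical event (IME) designations, and computes shrinkage-based
    reporting odds ratios and Bayesian information components with 95%
    lower bounds under two background contexts. Includes SOC-level and
    PT-level IME signal spectra, cohort characteristic tabulation,
    comedication-bin IME incidence, and a synthetic FAERS-like data
    generator with planted drug-event associations for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
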