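Package: fncohort
Title: Claims-Based Febrile Neutropenia Episode Identification, Classification, and Costing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds episodes of chemotherapy-induced febrile neutropenia (FN) from
    administrative claims: candidate detection from same-day neutropenia plus
    fever/infection diagnoses, qualification against chemotherapy lookback,
    continuous-enrollment and clean pre-period rules, episode termination with
    hospitalization extension, and inter-episode washout. Classifies each episode's
    chemotherapy FN-risk, prophylactic versus treatment GCSF and antimicrobial use,
    NCI Charlson comorbidity score, NCCN risk factors and cancer-type subgroups, and
    attributes all-cause and FN-related healthcare utilization and inflation-adjusted
    costs. Includes a seeded synthetic-claims generator with a ground-truth ledger so
    the full pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
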