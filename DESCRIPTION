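Package: trialaccess
Title: Geographic Barriers and Patient Representation in Clinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing geographic barriers to clinical trial
    participation and the representativeness of trial populations. Classifies
    care providers as research active under recruitment- and
    participation-based definitions, computes great-circle distance and travel
    burden from small-area population-weighted centroids to the nearest active
    provider (including the excess distance beyond the nearest care provider),
    fits ecological regressions of distance on area sociodemographics, pools
    published per-trial age and sex summaries (converting median/IQR reports
    to mean/SD), and compares trial enrolees with the incident patient
    population. Includes a synthetic-data generator with planted effects so
    every stage of the pipeline has a parameter-recovery test.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
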