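Package: briefhine
Title: Scoring and Diagnostic Accuracy for the 11-Item Brief-HINE Infant
    Neurological Screen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the Brief Hammersmith Infant Neurological Examination
    (Brief-HINE), an 11-item screening instrument for infants assessed at 3,
    6, 9, and 12 months. Implements the proforma data model with left/right
    asymmetry averaging, the global score (0-33), age-conditional warning
    signs with the 90th-centile derivation that justifies them, and the
    age-specific cut-off classifier for cerebral palsy risk. Includes the
    accompanying diagnostic-accuracy toolkit (Liu-method cut-point
    estimation, sensitivity/specificity/PPV/NPV/accuracy, Mann-Whitney AUC,
    stratified bootstrap confidence intervals) and a seeded synthetic cohort
    generator that emulates the published group-wise score distributions so
    the full analysis pipeline runs end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
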