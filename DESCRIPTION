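Package: rdocscore
Title: Lexicon-Based RDoC Scoring of Clinical Notes and Length-of-Stay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes dimensional psychopathology scores from psychiatric
    admission notes by matching a Research Domain Criteria (RDoC) term
    lexicon against normalized note text (presence-fraction scoring), and
    runs the downstream admission-level analyses: baseline group
    comparisons, per-domain ANOVA with post hoc t tests, covariate-adjusted
    linear regression, per-diagnosis logistic models of a dichotomized
    length of stay, and a secondary Cox model of time to discharge. Ships a
    synthetic-data generator that emulates the statistical structure of a
    three-diagnosis inpatient cohort with known planted truth, so every
    pipeline stage is testable without access to real electronic health
    records.
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
    stringi,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
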