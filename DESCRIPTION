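Package: aspredict
Title: Predicting Future Ankylosing Spondylitis Diagnoses from Coded Primary-Care Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable reimplementation of a machine-learning
    pipeline for profiling patients likely to receive a future diagnosis of
    ankylosing spondylitis (AS) from routinely collected coded health records.
    Includes a synthetic longitudinal EHR generator with plantable, sex-specific
    prodromal signatures; incident-case identification with back-dated suspected
    onset; 1:100 matched control-set construction; binary, time-sliced,
    multi-level code features; chi-squared stability selection over 100 matched
    cohorts followed by logistic-regression filtering and principal component
    analysis; decision trees fitted on component scores and selected by highest
    average F value; and prevalence-aware evaluation including positive
    predictive value deflation in low-prevalence populations and a 90/90
    "perfect model" comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
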