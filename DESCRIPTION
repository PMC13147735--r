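Package: asmdsit
Title: Suspicion Index Development and Validation for Acid Sphingomyelinase Deficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Development and internal validation of a symptom-based suspicion
    index for acid sphingomyelinase deficiency (ASMD, Niemann-Pick disease
    types A, A/B and B) from retrospective chart-review cohorts. Provides
    cohort containers with delimited-text input/output and descriptive
    summaries, a seeded synthetic-cohort generator with configurable
    within-patient symptom dependence, per-symptom exact-test screening
    (two-sided Fisher exact p-values, conditional maximum-likelihood odds
    ratios, Holm multiplicity correction), ridge-penalized multinomial
    logistic risk models over binary symptom predictors, events-per-variable
    capped best-subset stability selection across repeated train/test splits
    with a random-forest importance cross-check, a prerequisite-gated
    probability scoring tool, and bootstrap/ROC internal validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
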