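Package: tonescreen
Title: Two-Tone Hearing Screening Rules from Pure-Tone Audiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives parsimonious pure-tone hearing screening protocols for
    community-dwelling older adults from four-frequency air-conduction
    audiograms. Provides WHO severity grading and better/worse-ear labeling,
    a from-scratch depth-limited classification tree with Gini and Shannon
    impurity and weighted-impurity-decrease frequency importances, extraction
    of the fitted tree into an ordered two-step tone-presentation rule,
    simulated administration of screening rules, confusion-matrix evaluation
    (sensitivity, specificity, accuracy), fixed-cutoff comparison criteria,
    and a calibrated synthetic presbycusis cohort generator for end-to-end
    testing when study data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
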