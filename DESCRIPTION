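Package: cotmeta
Title: Evidence Synthesis for Cognition-Oriented Treatment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A file-based toolkit for coding, appraising and meta-analysing
    controlled trials of cognition-oriented treatments (cognitive training,
    stimulation and rehabilitation) in older adults.  Trials are stored as
    structured text records with controlled coding vocabularies; the package
    computes methodological quality indices (PEDro, Jadad, Cochrane Risk of
    Bias) from the coded items, standardized mean differences (Hedges' g)
    with subgroup combining, shared-control multi-arm adjustment and
    correlated-outcome composites, pools them with a random-effects model
    (REML heterogeneity, Hartung-Knapp-Sidik-Jonkman intervals, Q, I-squared,
    prediction intervals), grades the certainty of each pooled finding, and
    renders evidence-synthesis reports with forest plots.  A synthetic-trial
    generator with known ground truth supports calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
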