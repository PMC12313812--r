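Package: vocaleff
Title: Vocal Efficiency Analysis of Animal Call Sequences via the
    Menzerath-Altmann Law
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing the Menzerath-Altmann law (longer vocal
    sequences are composed of shorter elements) in annotated animal call
    recordings, developed around corvid call sequences. Reads Audacity
    label tracks and Raven Pro selection tables, segments calls into
    sequences by an inter-call silence threshold, computes per-individual
    dominance (Elo rating) and affiliation (composite sociality index)
    covariates from focal-observation logs, and fits hierarchical
    Gaussian models of log call duration on log sequence length with
    nested random intercepts and slopes, including AIC and
    likelihood-ratio model comparison. A synthetic-data generator with
    known ground truth supports parameter-recovery simulation and makes
    every pipeline stage testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
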