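Package: synopht
Title: Evaluation of Synergistic AI-Clinician Ophthalmic Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating rule-based ophthalmic screening against
    clinician assessments: simulation of multi-rater cup-to-disc ratio (CDR)
    cohorts with calibrated noise, gradability and tiered retinal-disease
    structure; vertical CDR morphometry from binary disc/cup segmentation
    masks; glaucoma-suspect, retinal-disease and media-opacity decision rules
    and their OR-combination; confusion-matrix metrics with paired bootstrap
    inference and exact integer reconstruction of confusion matrices from
    rounded published metrics; dual-threshold OR-synergy ROC envelopes; and
    Bland-Altman / correlation agreement analysis, orchestrated by a
    reproducible study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
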