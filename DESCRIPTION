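Package: notepheno
Title: Extraction of Verbal and Ambulatory Ability from Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for extracting binary functional biomarkers
    (verbal ability: does the individual use any words; ambulatory ability:
    can the individual walk without aid) from longitudinal clinical-note
    corpora using a pluggable language-model extractor. Covers note
    selection, score-leakage scrubbing, conversational prompt construction,
    assessment-based ground-truth mapping (CARS-2, telehealth screener,
    M-CHAT-R, GMFCS, Viking Speech Scale, CFCS), note-to-individual label
    aggregation by majority or any-yes rules, evaluation with weighted and
    macro F1, per-note-type informativeness analysis, and API token-cost
    estimation. Ships a synthetic EHR cohort generator with known latent
    abilities so every stage is testable without real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
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
    caret,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
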