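Package: icusepsis
Title: Sepsis-3 Phenotyping of ICU Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies sepsis and septic shock episodes in intensive care
    unit admissions from tabular electronic health record extracts, following
    the Sepsis-3 consensus definition. Provides daily Sequential Organ
    Failure Assessment (SOFA) scoring with explicit missing-data policies,
    antibiotic spectrum ranking and escalation detection with prophylaxis
    filtering (including selective digestive decontamination), episode
    deduplication and septic-shock classification, pre-specified sensitivity
    variants, cohort summary tables, and a synthetic ICU cohort generator
    with planted ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
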