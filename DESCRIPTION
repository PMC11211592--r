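Package: hepascan
Title: Disproportionality Analysis of Hepatitis Adverse Events Under
    Immune Checkpoint Inhibitor Therapy in FAERS-Style Report Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, configuration-driven pharmacovigilance pipeline for
    spontaneous adverse-event report data in the FAERS quarterly ASCII
    dialect: ingestion of DEMO/DRUG/REAC/OUTC/INDI/THER tables,
    FDA-recommended case deduplication, immune-checkpoint-inhibitor cohort
    and regimen construction, frequentist (reporting odds ratio with Wald
    interval) and Bayesian (information component with credibility bound)
    disproportionality signal detection over event-by-strategy grids,
    head-to-head subgroup contrasts, and descriptive case
    characterization. Includes a synthetic report generator with plantable
    drug-event odds ratios so the full pipeline is testable without any
    database download, and worked examples recomputing published
    hepatitis signal statistics from their 2x2 counts.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
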