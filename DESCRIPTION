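Package: phoenixscore
Title: Phoenix Pediatric Sepsis Score and Criteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Phoenix pediatric sepsis score and criteria from
    tabular patient-level data: the eight organ-dysfunction sub-scores
    (respiratory, cardiovascular, coagulation, neurologic, endocrine,
    immunologic, renal, hepatic), the 4-system Phoenix and 8-system Phoenix-8
    totals, and the score-based sepsis and septic-shock indicators, with
    age-adjusted mean-arterial-pressure and creatinine thresholds and
    missing-data-maps-to-zero semantics. Includes helpers to derive scorer
    inputs from raw vitals and labs (oxygenation ratios, mean arterial
    pressure, vasoactive-agent counts), a CSV/TSV scoring command-line tool
    with configurable column mapping, and a seeded synthetic-cohort
    generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
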