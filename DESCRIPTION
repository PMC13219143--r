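Package: pbagrisk
Title: Soil-Vegetable Lead Ingestion Risk Assessment for Urban Agrisystems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Human health risk assessment of lead (Pb) ingestion in urban
    agriculture. Accounts for oral bioaccessibility measured by the Unified
    BARGE Method (gastric and gastrointestinal phases), soil-to-plant transfer
    factors and regulatory guideline screening, deterministic risk indices
    (average daily intake, target hazard quotient, cancer slope risk) for
    soil-only, vegetable-only and combined exposure pathways, and a Monte
    Carlo uncertainty layer with tornado-style sensitivity rankings. Includes
    a synthetic replicate-level data generator emulating a 2 Pb-condition x
    2 amendment x 4 agrisystem pot experiment so the full pipeline is testable
    without access to raw measurements.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    tibble,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
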