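Package: acmscreen
Title: Questionnaire-Based Screening of Residential Asbestos-Containing Materials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative questionnaire engine for screening residential
    building materials for the probability that they contain asbestos.
    Ships a reconstructed three-module screening instrument covering eight
    outside and five inside locations, drives dwellings through it with
    conditional branching (skip logic, including an abbreviated outside-only
    pathway for houses built after 1990), classifies each material into one
    of four probability categories via per-material decision tables, scores
    possible and likely asbestos-containing materials through an additive
    condition-by-disturbance risk matrix into four priority levels with
    remediation recommendations, renders and stores per-house summary
    reports, and aggregates stored reports into survey-level summaries.
    Includes a seeded housing-stock simulator that generates
    branching-consistent synthetic answer sets for testing and
    survey-scale simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
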