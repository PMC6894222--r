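Package: arthrism
Title: Sensory and Motor Deficit Scales for Collagen-Induced Arthritis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and applying linear sensory/motor deficit
    scales in the collagen-induced arthritis (CIA) mouse model. Simulates
    longitudinal CIA-like cohorts (naive, adjuvant-only, untreated and
    methotrexate-treated arms), computes clinical scorecards, arthritis
    incidence, ACR-like arthritis-improvement (AI) responder classes and
    histology scores, normalizes functional readouts (withdrawal latency,
    traveled distance, paw print area, skin temperature) to naive references,
    fits pooled score-versus-function regressions, and turns the fits into a
    deficit scale that predicts relative sensory and motor deficits from the
    clinical score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
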