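Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for pharmacovigilance signal detection on
    FAERS-style spontaneous adverse-event report data. Parses the quarterly
    "$"-delimited ASCII extracts in both the legacy (LAERS) and current
    (FAERS) schema dialects, applies the standard case-version and exclusion
    cascade, builds drug-event pairs and 2x2 contingency tables against a
    configurable comparator universe, and computes three disproportionality
    indices - the proportional reporting ratio (PRR), the reporting odds
    ratio (ROR) with Wald intervals, and the Bayesian confidence propagation
    neural network information component (IC) - together with the standard
    signal criteria. Includes a logistic-regression risk-factor stage with
    the Hosmer-Lemeshow goodness-of-fit test, a synthetic report generator
    with planted drug-event associations for validation, and bundled
    reference contingency tables from a published piperacillin/tazobactam
    electrolyte-disorder screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
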