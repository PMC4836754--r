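Package: poleage
Title: Pole-Age Lineage Analysis and Demography of Bacterial Replicative Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-cell analysis of bacterial replicative aging in
    rod-shaped bacteria such as Escherichia coli, where individuals are defined
    by the age of their older cell pole. Reconstructs binary lineage trees from
    time-lapse tracking tables, assigns pole ages and pole-defined individual
    identities, applies an operational stop-of-division criterion, and computes
    per-division and cumulative stop probabilities with censoring. Includes an
    Euler-Lotka demographic model quantifying the population growth-rate cost
    of pole-age-specific mortality with a Leslie-matrix cross-check, windowed
    log-linear estimation of doubling times from optical-density growth curves,
    quantification of fluorescent-reporter signals (integrated density,
    cylinder-approximation concentration, quarter-cell long-axis profiles,
    mother/daughter division panels), and an agent-based simulator of
    time-lapse lineage data with mother-machine geometry, aggregate-like and
    chromosome-like reporter dynamics, and microplate growth curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
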