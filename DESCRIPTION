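Package: medflow
Title: Bayesian Network Flow Models for Medication-Error Incident Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for factor analysis of nurse medication-error incident
    reports with discrete Bayesian networks. Provides a fixed codebook of
    error events and contributing factors (attributional, system,
    conditional, and knowledge/behavioral categories), record validation and
    descriptive tabulation, exact inference by variable elimination with a
    joint-enumeration oracle, category-constrained greedy structure learning
    with blacklists and an edge-acceptance threshold, layer assignment for
    the learned flow model, scenario analysis that suppresses individual
    factors and reports posterior event probabilities, and a calibrated
    synthetic-data generator with a known ground-truth network for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
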