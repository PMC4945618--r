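Package: intagree
Title: Interval Agreement Aggregation of Structured Expert Elicitations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structured expert elicitation and risk screening based
    on the interval agreement approach. Interval-valued elicitation records
    (lowest, best and highest estimates with a stated confidence) are
    standardized to derived confidence intervals by linear extrapolation,
    experts are calibrated against known-answer questions, and calibrated
    intervals are aggregated per item into a piecewise-constant agreement
    function from which crisp likelihood summaries (min-max, max-max,
    centroid) are extracted. A risk-factor by biological-element matrix
    orchestrates screening, per-combination aggregation and risk-factor
    rankings, with agreement-graph and bipartite-network outputs. Includes a
    seeded synthetic panel generator so every stage is testable without a
    workshop dataset, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
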