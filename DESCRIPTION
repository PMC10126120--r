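Package: inflamnet
Title: Dynamic Network and Hypergraph Analysis of Multi-Compartment Inflammation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers dynamic inflammatory networks from longitudinal multiplex
    cytokine panels measured in two tissue compartments (serum and wound
    effluent). Implements correlation-threshold interval networks (DyNA) with
    network-complexity and Shannon-entropy scores, dynamic hypergraphs (DyHyp)
    that map per-mediator time trends onto compartment sets, Spearman
    rank-correlation inference of IL-17A-producing cell subsets with bootstrap
    confidence intervals, per-mediator two-way ANOVA screening, exact
    contingency-table tests, and a synthetic-cohort generator with planted
    correlation structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    car,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
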