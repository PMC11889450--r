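Package: minnet
Title: Minimal Network Enrichment Analysis for Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Enumerates alternative minimum-size subnetworks (minimal
    networks, MiNs) of a constraint-based metabolic model that accomplish a
    metabolic task -- synthesis of a target metabolite or of a biomass
    building block -- and ranks them by enrichment of context-specific gene
    expression using a multivariate hypergeometric test. Includes an SBML
    (Level 3, FBC) reader and writer, flux variability analysis with
    blocked-reaction pruning, gene-protein-reaction rule evaluation onto
    reaction-level expression, a built-in exact mixed-integer linear
    programming solver with integer-cut enumeration of alternative optima,
    and generators for toy models and synthetic expression tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
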