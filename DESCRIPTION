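Package: gemverify
Title: Exact Verification of Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A verification toolkit for genome-scale constraint-based metabolic
    models. Parses SBML reconstructions in the legacy COBRA dialect and in SBML
    Level 3 with the Flux Balance Constraints (fbc) version 2 package, with
    explicit control over the boundary-condition convention; proves or refutes
    biomass-producing feasibility with an exact rational-arithmetic simplex
    alongside floating-point linear programming; computes thermodynamically
    consistent (loopless) flux states and converts loopy optima into loopless
    ones without changing the objective; and lints models for the file-encoding
    defects (case-colliding metabolite identifiers, misused boundary flags,
    inverted bounds) that masquerade as numerical infeasibility.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
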