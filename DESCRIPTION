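Package: flowsafety
Title: Safe Paths for Minimum Flow Decompositions of Splice Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes all maximal safe paths for minimum flow decompositions
    (MFD) of acyclic flow networks, such as the splice graphs used in RNA
    transcript multiassembly. A safe path is one contained in some path of
    every minimum-size decomposition of the flow into weighted source-to-sink
    paths; safe paths are the parts of the transcripts that any parsimonious
    assembly must report. Safety of a group of candidate paths is decided by a
    single integer linear program that maximises the number of simultaneously
    avoidable paths, wrapped in a recursive group-testing procedure and a
    top-down trimming algorithm over an initial minimum decomposition.
    Includes the MFD integer program itself (with optional subpath
    constraints), Y-to-V contraction and funnel shortcuts, the excess-flow
    safety test for all flow decompositions, baselines (extended unitigs,
    safe-for-all-FD paths), a synthetic splice-graph generator with known
    ground truth, brute-force enumeration oracles, and transcript-recovery
    quality metrics (weighted precision, maximum coverage, F-score). A small
    branch-and-bound solver over a two-phase simplex (C++) backs the integer
    programs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
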