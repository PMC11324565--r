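Package: pcbdechlor
Title: Congener-Level Analytics for Microbial PCB Reductive Dechlorination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies microbial reductive dechlorination of polychlorinated
    biphenyl (PCB) mixtures from congener mole-percent time courses.
    Enumerates and numbers all 209 congeners under biphenyl symmetry, computes
    average chlorines per biphenyl, chloride-release rates, and positional
    (ortho/meta/para) chlorine-removal accounting; builds single-removal
    dechlorination reaction networks with reachability queries and rule-based
    process (N, H/H') classification; simulates first-order kinetic congener
    time courses with an exact chloride-release ledger and synthetic
    compositional taxon-abundance tables with planted rank correlations; and
    assembles thresholded Spearman co-occurrence networks with standard
    topology metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
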