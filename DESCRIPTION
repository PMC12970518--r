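Package: cooppool
Title: Group-Testing Designs and Deconvolution for Cooperative Compound
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Tools for discovering rare cooperative interactions (typically
    pairs) in compound libraries by pooled screening. Constructs covering
    designs in which every pair (or triple) of candidates occurs in at least
    one pool, using a greedy constructor and a swap-based local search;
    resolves positive pools by adaptive iterative sectioning or by a
    non-adaptive one-step signature design; models a luminescence-quenching
    readout with additive Stern-Volmer background to choose pool sizes and
    hit thresholds; simulates complete screening campaigns with planted
    ground truths; and compares reaction GC-MS peak tables against control
    runs to flag new product peaks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
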