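Package: sagescore
Title: Coverage-Sensitive Scoring of Predicted Genome Templates
Version: 0.1.0
Authors@R:
    person("SAGE", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores predicted genomic sequences (templates) of complex,
    repetitive regions against a short-read set by solving a
    coverage-sensitive many-to-many min-cost bipartite matching problem
    (CSM). Reads are matched to fixed-length template segments so that
    the total of alignment costs plus convex per-segment
    coverage-deviation costs is minimised; the convex case is solved
    exactly by reduction to min-cost integer flow. Includes a builder
    that turns SAM/BAM multi-mappings into CSM instances, a naive
    best-alignment baseline score, template ranking utilities, and a
    synthetic simulator of KIR-like multi-copy haplotypes with
    paired-end reads and an exhaustive internal mapper, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
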