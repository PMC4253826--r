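Package: lrec
Title: Hybrid Error Correction of Long Sequencing Reads with a de Bruijn
    Graph
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Corrects long, indel-rich sequencing reads (such as PacBio
    reads) with the help of accurate short reads.  The short reads are
    summarised as a de Bruijn graph over solid k-mers; erroneous (weak)
    regions of each long read are replaced by the sequence spelled by an
    optimal graph path, found by a bounded depth-first search that scores
    candidate paths with an incremental edit-distance dynamic programme.
    Bridging paths between solid anchors are assembled into a per-read
    path graph whose shortest path selects the applied corrections; read
    ends are corrected by one-sided extension searches.  The package also
    provides trimming and splitting of corrected reads, a read simulator
    with an insertion-skewed long-read error model, and a position-level
    evaluator reporting correction sensitivity and gain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
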