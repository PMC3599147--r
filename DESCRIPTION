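Package: mttr
Title: Tandem Repeats in Mitochondrial Genomes: Detection, Survey
    Statistics, Clone Comparison and a Pause-Melting Misalignment
    Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis of tandem repeats (TRs) in circular
    vertebrate mitochondrial genomes. Detects tandem arrays with a
    wraparound dynamic-programming scorer (match +2, mismatch -7,
    indel -7, report threshold 50), classifies tracts by genomic
    context on annotated genomes (control-region 3'/5' ends, CDS,
    tRNA, rRNA, intergenic), aggregates survey tables and motif-length
    histograms, encodes control-region clone tracts over a motif
    alphabet to call motif indels with ambiguity intervals, detects
    the birth signature of newly generated repeats, and
    forward-simulates the Pause-Melting Misalignment (PMM) model of
    repeat birth and motif indel. A synthetic-data module generates
    annotated genomes with planted repeats and flounder-style clone
    sets so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
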