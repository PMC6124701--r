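Package: orgEGT
Title: Organellar Genome Assembly and Endosymbiotic Gene Transfer Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bait-and-iterate assembly of plant organellar genomes from
    short paired-end reads, exact duplicated-region quantification,
    syntenic-block and rearrangement mapping between mitogenomes, and
    detection and summarization of endosymbiotic transfers (MTPTs, NUMTs
    and NUPTs) among the plastome, mitogenome and nuclear genome. Includes
    a seed-and-extend local aligner with Karlin-Altschul E-values, a
    synthetic-data generator with a ground-truth event log for recovery
    benchmarking, and an end-to-end pipeline producing per-chromosome and
    per-compartment transfer summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
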