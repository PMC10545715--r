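Package: dualseq
Title: Dual RNA-Seq Read Partitioning, Reference Polishing and Temporal
    Co-Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational workflow of a dual RNA-seq
    host-pathogen infection study: simulation of mixed-origin sequencing
    data with recorded ground truth, sliding-window quality trimming,
    a seed-and-extend read aligner with a linear score threshold and a
    unique-mapping contract, sequential two-genome read partitioning,
    iterative SNP correction of a strain-divergent host reference with
    Phred-scaled variant calls and a SNP-aware final index, FPKM
    quantification with replicate pooling and presence-set (Venn)
    analysis, UPGMA co-expression clustering with Davies-Bouldin cluster
    number selection, and closed-form mortality (Abbott) and qPCR (NRQ)
    calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
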