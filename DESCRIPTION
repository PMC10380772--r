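Package: spliceCensus
Title: Alternative-Splicing Event Census and Methylation Profiling for Cotton Fiber Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable downstream pipeline for genome-wide alternative-splicing
    (AS) analysis of allotetraploid cotton ovule and fiber development. Consumes
    rMATS-style junction-count tables, GTF annotation, genome FASTA, BLAST
    tabular hits and per-cytosine methylation calls; computes percent-spliced-in
    (PSI) from inclusion and skipping junction counts, applies retention
    thresholds, and derives event and gene censuses across tissues, stages and
    the At/Dt subgenomes; pairs homoeologs by reciprocal best hit; compares gene
    length, exon count and GC content of spliced versus constitutively spliced
    genes, including the GC microenvironment of splice junctions; normalizes
    counts to TPM and performs hypergeometric term enrichment; and builds
    context-resolved (CpG/CHG/CHH) sliding-window methylation profiles over gene
    bodies, flanks and splice junctions. A synthetic-data generator emulates the
    statistical structure of the study inputs so the full pipeline is testable
    without any raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
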