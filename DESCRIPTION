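Package: sirnaq
Title: Small RNA-Seq siRNA Quantification, Cluster Discovery and Hairpin
    Phasing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for analysing small RNA sequencing
    libraries dominated by miRNAs and hairpin-derived siRNAs. Implements
    deterministic two-round trimming of NEXTflex-style reads (3' adapter
    removal followed by removal of the 4-nt randomized ends), exact-match
    placement of 15-30 nt reads on a genome plus transfected plasmid
    sequences with all placements of multimapping reads retained,
    fractional (1/n) read counting with reads-per-million normalization,
    discovery of 21-23 nt small RNA clusters (collapse overlapping reads,
    discard regions below 3 RPM, join clusters within 50 bp, intersect
    across replicates, merge across samples by coordinate union),
    hierarchical cluster annotation (miRNA > transposable elements > mRNA
    > misc RNA > other), per-position siRNA density profiles over
    inverted-repeat hairpin arms, selection of reporter-antisense siRNAs,
    and a modulo-22 phasing-register statistic for detecting processive
    end-entry Dicer cleavage. A deterministic synthetic-data generator
    produces toy references, annotations and FASTQ libraries with full
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
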