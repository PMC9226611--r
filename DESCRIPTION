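Package: tnseqr
Title: Gene Essentiality Analysis for Mariner Transposon Insertion Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for Tn-seq gene essentiality screens built
    on MmeI-liberated mariner (Himar1) transposon junction reads. Enumerates
    candidate TA dinucleotide insertion sites and flags sites whose 14-mer
    context is not unique, extracts short genomic inserts from raw junction
    reads, maps them by exact unique placement, tabulates insertion reads per
    gene under a first-95%-of-gene rule, normalizes to reads per kilobase per
    10 million uniquely mapped reads, and classifies genes as essential,
    growth-defective, neutral, or growth-advantaged from an outlier-trimmed
    normal fit of log2 normalized abundance per replicate, with replicate
    consensus and cross-condition set analysis (core essential genome,
    condition-specific essential sets, UpSet-style membership counts). A
    synthetic-data generator produces genomes, mutant libraries, and raw reads
    with a ground-truth ledger so every stage is testable without external
    downloads. Includes a heme-binding-motif (CX(2-4)CH) proteome scanner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
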