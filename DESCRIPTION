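Package: iclipr
Title: Crosslink-Site Analysis of iCLIP Data for mRNA Export Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing individual-nucleotide-resolution UV
    crosslinking and immunoprecipitation (iCLIP) data of RNA-binding
    proteins such as the mRNA export machinery. Converts deduplicated
    alignments into stranded single-nucleotide crosslink tracks, calls
    significantly crosslinked bases by within-region randomization FDR,
    scores kmer enrichment with control-corrected z-scores, computes
    splicing and 3' processing indices from junction-spanning reads and
    poly(A)-site windows, builds metagene and exon-junction profiles,
    estimates category enrichments with bootstrap confidence intervals,
    identifies retained and detained introns (the latter against an
    effective-length-weighted in-silico null with a negative-binomial
    test), and summarises alternative polyadenylation as
    expression-weighted transcript lengths. Includes a synthetic-data
    generator that plants known peaks, motifs, retained/detained introns
    and usage shifts so every pipeline stage can be validated without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
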