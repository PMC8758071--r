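Package: syngc
Title: Synteny, Codon GC Content and Gene-Body Methylation in Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links gene duplication history to genic GC content and
    cytosine methylation. Detects collinear syntenic blocks between gene
    orders by dynamic-programming anchor chaining, classifies genes as
    syntenic or non-syntenic, computes third-codon-position GC content over
    the first fifty codons (GC3-50), estimates within-genome copy number of
    gene 5' ends, computes weighted CG/CHG/CHH methylation levels over the
    first 150 bp of each transcript, and ties the pieces together with
    rank-sum tests, correlations and GO-term enrichment. Includes a
    synthetic genome-pair generator with full ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
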