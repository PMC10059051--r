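Package: isoannot
Title: Structural Annotation of Full-Length Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for structural annotation of full-length transcriptome
    (Iso-Seq style) data: collapse of mapped full-length reads into gene
    loci and non-redundant isoforms by a strand-aware overlap rule,
    novelty classification against a reference annotation, alternative
    splicing event typing (exon skipping, intron retention, alternative
    donor/acceptor, mutually exclusive exons), alternative polyadenylation
    site clustering with flanking-sequence profiling, positional
    classification of long non-coding RNAs, and transcript- versus
    gene-level differential expression with their overlap statistic.
    Includes a synthetic-data generator that emits toy annotations,
    genomes, simulated full-length read alignments and count matrices so
    every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    igraph,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
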