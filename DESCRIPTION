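Package: PanSV
Title: Structural Variant Discovery and Pan-Genome Composition from
    Short-Read Signatures
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls deletions and transposable-element insertions from
    paired-end mapping signatures, tests genic copy-number variation from
    depth-of-coverage fragment counts with a negative-binomial exact test,
    classifies variant sequences against repeat annotations and element
    libraries, dates LTR retrotransposons from terminal-repeat divergence,
    contrasts expression and dN/dS of affected genes by randomization, and
    composes a multi-accession pan-genome into core and dispensable
    fractions. A synthetic-genome generator plants structural variants with
    full ground truth and emulates paired-end alignments, enabling
    end-to-end recovery benchmarking of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr,
    DESeq2,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
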