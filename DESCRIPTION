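Package: panelseq
Title: Amplicon Panel Sequencing Toolkit for Hereditary-Cancer Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational core of a multiplexed-amplicon next-generation
    sequencing panel for germline testing of hereditary-cancer genes.
    Implements demultiplexing, quality trimming, pseudogene-aware read
    assignment, threshold-based zygosity calling with coverage flags,
    large-rearrangement detection from amplicon read-count dosage across a
    batch, an orthogonal microarray CGH normalization stack with region
    calling, PCR allele-dropout flagging, and analytical-validation
    statistics with exact one-sided binomial confidence bounds. A synthetic
    data module generates panels, references with pseudogene homologs,
    reads, count matrices and probe tables with known ground truth so the
    whole pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
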