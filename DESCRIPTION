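Package: gbskit
Title: Components for Two-Enzyme Genotyping-by-Sequencing Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable, tested building blocks for reduced-representation
    genotyping-by-sequencing (GBS) with a rare-cutter/common-cutter enzyme
    pair. Provides in silico single and double restriction digests with
    fragment classification and protocol comparison, inline-barcode
    demultiplexing of paired-end reads with restriction-remnant validation,
    merging of per-sample variant calls into a genotype dosage matrix, a
    filter cascade (repeat masking, missingness, minor allele frequency,
    linkage-disequilibrium pruning) with full per-stage accounting,
    allele-sharing distances, neighbour-joining trees with column-resampling
    bootstrap support, Evanno delta-K model choice over external clustering
    likelihoods, a replicate/taxon authenticity audit, and seeded generators
    for synthetic genomes, barcoded read pairs and structured populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
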