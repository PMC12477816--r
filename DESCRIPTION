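Package: telandscape
Title: Transposable Element Landscape Characterization and Regulation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the transposable element (TE) landscape of a
    genome from a consensus library and RepeatMasker-style hits: consensus library
    post-processing (greedy identity/coverage clustering, cluster-based
    reclassification, tandem-repeat purging, redundancy removal, majority-rule
    consensus building), defragmentation of repeat hits into copy-level
    annotations with intactness classification and divergence landscapes,
    windowed chromosomal and compartment density statistics (sex chromosome,
    pseudoautosomal and sex-determining regions, subtelomere profiles,
    cut-and-paste versus copy-and-paste abundance ratios, superfamily
    enrichment), gene-context analyses (site-class partitioning, TE-gene
    proximity, genic TE:CDS ratios, gene-age contingency), and small-RNA and
    histone-mark association statistics (full-containment multi-overlap read
    counting, CPM, peak overlap fractions, conditional intersection proportions,
    scale-regions metaprofiles, consensus-feature coverage). A synthetic
    mobilome simulator with a complete truth table supports end-to-end
    validation against planted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
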