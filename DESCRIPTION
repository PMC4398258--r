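Package: cageatlas
Title: CAGE Promoterome Analysis: TSS Atlases, Coexpression Clustering and
    Bidirectional Enhancer Calling
Version: 0.1.0
Authors@R:
    person("Atlas", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Builds multi-sample promoter atlases from stranded CAGE
    (cap analysis of gene expression) 5' tag count tracks: distance-based
    tag clustering into TSS regions, tags-per-million normalisation and
    expression filtering, strand-aware promoter/intragenic/intergenic
    annotation, alternate-promoter usage statistics, Pearson
    correlation graphs clustered with the Markov cluster algorithm,
    cis-regulatory motif and interval-overlap enrichment via
    hypergeometric tests with false discovery rate control, candidate
    enhancer calling from balanced bidirectional transcription with
    cell-type restriction and coexpression-based gene linking, and
    stage-ordered trajectory clustering.  Ships a synthetic CAGE data
    generator that plants recoverable modules, motifs and enhancers for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
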