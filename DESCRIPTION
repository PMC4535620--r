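Package: serosom
Title: Serotype Transcriptome Landscapes from Self-Organizing Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-condition bulk RNA-seq of ciliate
    serotype cultures: expression-unit conversion (TPM/RPKM) and
    median-of-ratios normalization, negative-binomial Wald differential
    expression with Benjamini-Hochberg control, self-organizing-map
    transcriptome landscapes with regulated-spot detection on a 20x20
    lattice, surface-antigen co-regulation and spot-persistence statistics,
    dual-metric (Euclidean and 1-Pearson) hierarchical clustering,
    subtelomeric position-effect scans with a permutation test for
    heterochromatic spreading, and GO enrichment by term-for-term and
    parent-child-union hypergeometric tests. Includes a seeded synthetic
    data generator with ground-truth labels that emulates the study design
    the pipeline targets (seven conditions, three replicates, a mutually
    exclusive eight-gene surface-antigen family, planted co-regulated
    modules, condition programs and subtelomeric layouts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
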