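Package: stabilityqtl
Title: Simultaneous Mapping of Expression and mRNA Stability QTLs from
    Exon and Intron Read Counts
Version: 0.1.0
Authors@R:
    person("stabilityqtl", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers relative mRNA stability per gene and sample from paired
    exonic and intronic RNA-seq read counts (exon-intron split analysis with
    a linear expression-dependent bias correction), maps cis quantitative
    trait loci for expression and stability traits with ordinary
    least-squares dosage models and Benjamini-Hochberg false discovery
    control, cross-classifies the two QTL types with direction concordance,
    builds r-squared LD blocks with representative-QTL filtering, tests
    genic-region and RNA-binding-protein binding-site enrichment, and
    classifies sex-specific stability QTLs by sex-stratified and
    genotype-by-sex interaction models. A negative-binomial transcription /
    decay kinetic simulator with LD-structured genotypes and planted genetic
    effects provides a fully synthetic test bed and truth tables for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
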