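Package: melanomics
Title: Somatic Mutation Analysis of Tumor/Normal Melanoma Genomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of a melanoma
    tumor/normal whole-genome somatic mutation analysis. Provides Bayesian
    per-site genotype (MPG) and variant (MPV) scoring from pileup evidence,
    somatic SSNV and indel detection with normal-lookup, indel-proximity and
    strand-bias validation filters, tile-based somatic copy-number calling
    with cross-sample specificity filtering, tumor purity estimation from
    somatic allele fractions, UV mutational-spectrum and transcribed-strand
    bias analysis, block-sampling enrichment of mutations in functional
    annotations, hierarchical genic-landmark partitioning, and cross-cell-type
    DNase hypersensitive site clustering. A synthetic tumor/normal generator
    reproduces the statistical structure the pipeline assumes so that every
    stage is verifiable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
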