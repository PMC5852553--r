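Package: poolrfi
Title: Pool-Sequencing Screens and Pedigree Validation of Residual Feed
    Intake Variants
Version: 0.1.0
Authors@R:
    person("poolrfi", "contributors", email = "poolrfi@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping genomic variants associated with residual
    feed intake (RFI) in poultry from pooled whole-genome sequencing of
    phenotypic extremes. Computes RFI by least-squares regression of feed
    intake on metabolic body weight and weight gain, selects divergent
    birds and builds replicate DNA pools, screens pooled allele counts
    with replicate ANOVA, Benjamini-Hochberg adjustment, pairwise pooled
    F_ST and an allele-frequency-divergence cutoff, assigns candidate
    SNPs to genes within a +/-50 kb window with codon-level variant
    categorization, validates candidates in an independent pedigreed
    population via animal-model BLUP breeding values, Wald tests and
    additive/dominance decomposition of genotype least-squares means, and
    compares expression between groups with the 2^-ddCt method. A
    synthetic-data module generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    SummarizedExperiment,
    tools,
    utils,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
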