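Package: poolscape
Title: Pooled-GBS Germplasm Characterization, Quantitative Genetics and
    Landscape Genomics
Version: 0.1.0
Authors@R:
    person("Margot", "Field", email = "maintainer@poolscape.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for germplasm collections genotyped by pooled
    genotyping-by-sequencing. Estimates population allele frequencies from
    pooled read counts with replicate merging, SNP filtering and mean
    imputation; computes Modified Rogers Distances, expected heterozygosity,
    pairwise FST with gene-flow estimates and hierarchical AMOVA; performs
    DAPC-style clustering (PCA, a-score PC selection, k-means with BIC,
    discriminant memberships); builds VanRaden genomic and pedigree numerator
    relationship matrices; fits Gaussian mixed models by average-information
    REML with a genomic covariance for population effects, yielding variance
    components, GBLUPs and narrow-sense heritability; and runs redundancy
    analysis landscape genomics with collinearity pruning, candidate-SNP
    detection, association assignment with FDR control and nearest-gene
    annotation. A seeded synthetic-data generator emulates the statistical
    structure of a multi-environment pooled-GBS germplasm study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    vegan,
    lme4,
    withr
Config/testthat/edition: 3
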