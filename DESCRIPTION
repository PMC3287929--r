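Package: raretag
Title: Tagging of Rare Variants by Common SNPs via Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("raretag", "developers", email = "raretag@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of how well common SNPs (minor allele
    frequency > 0.05) tag rare variants (minor allele frequency < 0.01)
    through linkage disequilibrium. Stage one computes, within fixed
    genomic bins, the maximum single-SNP r-squared and the multiple
    R-squared between common-SNP dosages and the per-individual count (or
    presence) of rare alleles in random rare-SNP subsets, with a
    within-bin permutation null compared by Kolmogorov-Smirnov and t
    tests. Stage two builds, around each rare SNP, nested common tag-SNP
    sets pruned at two pairwise r-squared ceilings and tests the gain in
    multiple correlation with a nested-model F statistic, evaluated both
    analytically and against a block-permutation null that preserves LD
    within the added set. A haplotype-mosaic simulator with
    Balding-Nichols subpopulation divergence generates genotype data with
    known tagging structure so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Config/testthat/edition: 3
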