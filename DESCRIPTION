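Package: snpher
Title: SNP-Heritability Estimation and Genome Partitioning via GREML
Version: 0.1.0
Authors@R: person("snpher", "developers", role = c("aut", "cre"),
    email = "snpher-dev@example.org")
Description: Whole-genome estimation and partitioning of the phenotypic
    variance tagged by common SNPs in population cohorts. Provides SNP
    quality control (missingness, minor allele frequency, exact
    Hardy-Weinberg test), genetic relationship matrix (GRM) construction
    from PLINK files, relatedness pruning, covariate adjustment of
    quantitative traits, single- and multi-component restricted maximum
    likelihood (AI-REML) estimation of variance components with
    likelihood-ratio tests, partitioning of SNP heritability across
    chromosomes and genic/intergenic regions, genome-wide association
    scans with p-value enrichment summaries, and a polygenic
    genotype-phenotype simulator for validating the full pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
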