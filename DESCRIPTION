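Package: portaPRS
Title: Multi-Ancestry Meta-Analysis, Fine-Mapping and Polygenic Score
    Portability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for studying why polygenic scores
    transfer poorly across ancestries, exercised on simulated
    multi-population cohorts. Implements per-study GWAS of an
    inverse-rank-normalized quantitative trait, fixed-effects
    inverse-variance-weighted meta-analysis with double genomic control,
    approximate Bayes-factor fine-mapping with 99% credible sets,
    clumping-and-thresholding polygenic score construction and
    evaluation, and PRS-by-sex/region/lifestyle interaction models. A
    companion simulator generates multi-population genotype/phenotype
    cohorts with Balding-Nichols allele-frequency divergence,
    population-specific linkage-disequilibrium decay, a shared polygenic
    architecture, sex-dimorphic genetic effects and gene-environment
    interactions, so every stage is testable without access-controlled
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'assoc.R'
    'io.R'
    'prs.R'
    'interact.R'
    'finemap.R'
    'meta.R'
    'synthdata.R'
    'pipeline.R'
    'experiments.R'
    'methods.R'
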