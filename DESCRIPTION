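Package: dyneqtl
Title: Condition-Dynamic eQTL Mapping, Regulatory Hierarchy and Mendelian
    Randomization for Multi-Environment Expression GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for expression GWAS across multiple
    stress conditions: genotype quality control for inbred association
    panels, quantile and inverse-normal expression normalization, mixed
    linear model eQTL scanning with P3D variance components (IBS kinship,
    genotype-PC structure covariates and residual-expression hidden
    factors), consolidation of significant SNPs into eQTLs with
    local/distant and static/dynamic classification, a transcription-factor
    regulatory hierarchy built from distant eQTLs, a two-stage
    least-squares Mendelian randomization test linking instrumented
    expression to a quantitative phenotype, and candidate-region haplotype
    and linkage disequilibrium analysis. A synthetic-data generator with a
    known regulatory architecture (structured subpopulations, distance-
    decaying LD, condition-activated local and TF-mediated distant
    effects, hidden confounding factors, and an expression-mediated
    phenotype) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    igraph,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
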