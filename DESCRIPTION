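Package: haplocis
Title: Haplotype-Resolved Cis-Regulatory Analysis of Allele-Specific
    Expression and Chromatin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting cis-regulatory variation between the two
    haplotypes of a heterozygous (hybrid) genome. Implements ancestry
    assignment and imputation over phase blocks, allele-specific
    expression and chromatin-accessibility calling with a beta-binomial
    null calibrated on whole-genome sequencing counts and Stouffer
    pooling of per-SNP effects, construction of a gene-by-factor matrix
    of chromatin quantities over gene-relative regions, elastic-net
    modelling of expression from chromatin features with the lambda-1SE
    reduction, structural-variant to gene linkage with Hedges-g
    permutation tests, and matched-background permutation enrichment of
    trait-associated SNPs in accessible chromatin. A synthetic-data
    generator with known ground truth exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    glmnet,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
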