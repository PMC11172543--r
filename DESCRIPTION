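Package: burdenscan
Title: Deleterious SNP Identification and Mutation Burden Estimation in
    Germplasm Collections
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies predicted deleterious SNPs (dSNPs) from
    variant-effect annotations (SIFT scores on canonical transcripts)
    combined with evolutionary constraint (GERP rejected-substitution
    scores), estimates per-sample mutation burdens from a biallelic SNP
    genotype matrix, summarises the carrier-frequency spectrum of
    deleterious alleles, computes per-sample average pairwise genetic
    differences (APD), and characterises burden patterns across germplasm
    groups with one-way ANOVA, burden-APD correlation, and a
    selection-target-zone rule for genebank management. Includes a
    planted-truth synthetic data generator so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
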