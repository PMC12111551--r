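Package: pleioscan
Title: Cross-Disorder Screen for Germline Variants with Opposite Effects on
    Cancer and Autoimmune Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for screening genome-wide association study
    (GWAS) summary statistics for germline variants whose alleles have
    opposite effects on cancer and autoimmune/autoinflammatory disease
    (antagonistic pleiotropy). Implements sign-flipped fixed-effect
    inverse-variance-weighted meta-analysis with Cochran's Q heterogeneity
    filtering and dual significance thresholds, plink-style greedy LD
    clumping with locus merging, nearest-gene and immune gene-set
    annotation with hypergeometric pathway overrepresentation, Spearman
    correlation of candidate-gene tumor expression with immune-infiltration
    markers for target prioritization, and allele-aligned eQTL
    direction-of-effect classification. A seeded synthetic-data generator
    produces LD-structured genotypes, paired case-control summary
    statistics with planted effect classes, gene annotations, gene sets,
    latent-factor expression matrices and eQTL records so the whole screen
    can be exercised and calibrated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
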