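Package: pgirs
Title: Polygenic and Gene-Environment Interaction Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for constructing and evaluating polygenic and
    gene-environment interaction risk scores (PGIRS) from genotype dosage data.
    Provides per-SNP quality control (call rate, Hardy-Weinberg exact test,
    minor allele frequency), a genome-wide SNP association and SNP-environment
    interaction scan under an ordinary least squares model, P-value-ordered
    greedy LD clumping, PRS/GIRS/PGIRS score construction, stratified
    standardized association testing with Benjamini-Hochberg FDR control,
    product-of-coefficients mediation analysis with bootstrap intervals,
    k-fold cross-validated model evaluation, and a synthetic cohort generator
    with LD-blocked dosages and zero-inflated exposures so the whole pipeline
    is testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
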