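Package: aquagp
Title: Heritability, Association and Genomic Prediction for Full-Sib
    Aquaculture Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Animal-model quantitative genetics for the full-sib family
    designs typical of aquaculture breeding programs.  Builds pedigree (A)
    and VanRaden genomic (G) relationship matrices, estimates variance
    components and heritability by restricted maximum likelihood with an
    eigendecomposition-based single-random-effect solver, runs two-step
    GRAMMAR mixed-model association scans with Bonferroni significance
    thresholds and SNP-effect / variance-explained follow-up, and compares
    GBLUP against PBLUP breeding-value prediction by k-fold cross-validation
    across marker densities.  Includes a gene-dropping simulator of full-sib
    populations with correlated polygenic traits for method validation, plus
    readers and writers for PLINK PED/MAP genotypes and plain-text pedigree
    and phenotype tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
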