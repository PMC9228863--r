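Package: fadsmets
Title: Fatty Acid Profile Clustering and FADS1/FADS2 Haplotype Association
    for Metabolic Syndrome Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers metabolic-syndrome phenotypes by stepwise linear
    discriminant variable selection (Wilks' lambda criterion) and Ward
    minimum-variance clustering of plasma-phospholipid fatty acid profiles,
    and tests FADS1/FADS2 SNP genotypes, alleles and EM-inferred haplotypes
    for association with those phenotypes. Includes Hardy-Weinberg testing,
    pairwise linkage disequilibrium (D, D', r-squared) with contiguous block
    partitioning, Pearson chi-squared contingency tests with Yates continuity
    correction and Benjamini-Hochberg adjustment, max-statistic permutation
    correction for haplotype association, desaturase activity indices, and a
    synthetic cohort generator with haplotype-structured genotypes and
    cluster-dependent fatty acid distributions for fully reproducible runs
    without individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
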