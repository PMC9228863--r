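# Contingency machinery: genotype/allele tables, Pearson/Yates chi-squared,
# Hardy-Weinberg, BH adjustment and the association scan.

test_that("chi-squared agrees with the stats::chisq.test cross-check", {
  set.seed(1)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 30) + 1, 2, 3)
    ours <- pearson_chi2(tab, "none")
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_raw, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$expected, unname(ref$expected), ignore_attr = TRUE)
    tab2 <- matrix(rpois(4, 20) + 1, 2, 2)
    expect_equal(pearson_chi2(tab2, "yates")$chi2,
                 unname(suppressWarnings(
                   chisq.test(tab2, correct = TRUE))$statistic),
                 tolerance = 1e-12)
  }
})

test_that("chi-squared invariances and margins behave as required", {
  tab <- rbind(c(30, 10, 5), c(12, 18, 9))
  x <- pearson_chi2(tab, "none")$chi2
  expect_equal(pearson_chi2(tab[2:1, ], "none")$chi2, x)
  expect_equal(pearson_chi2(tab[, c(2, 1, 3)], "none")$chi2, x)
  expect_equal(pearson_chi2(10 * tab, "none")$chi2, 10 * x)
  # expected table preserves margins
  res <- pearson_chi2(tab, "none")
  expect_equal(rowSums(res$expected), rowSums(res$observed), tolerance = 1e-9)
  expect_equal(colSums(res$expected), colSums(res$observed), tolerance = 1e-9)
  # Yates shrinks the statistic when all deviations exceed 0.5
  t2 <- rbind(c(30, 10), c(12, 25))
  expect_lt(pearson_chi2(t2, "yates")$chi2, pearson_chi2(t2, "none")$chi2)
  # doubled counts: uncorrected doubles, Yates stays within [0, uncorrected]
  y2 <- pearson_chi2(2 * t2, "yates")$chi2
  expect_lte(y2, pearson_chi2(2 * t2, "none")$chi2)
  expect_gte(y2, 0)
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2)), "none"), "margin")
  expect_error(pearson_chi2(rbind(c(1, 0), c(2, 0)), "none"), "margin")
  expect_error(pearson_chi2(matrix(1, 2, 3), "yates"), "2x2")
})

test_that("genotype tables count (AA, Aa, aa) by the declared major allele", {
  cc <- reference_genotype_counts("mets_clusters")
  built <- counts_to_genotypes(cc, c("MetS1", "MetS2"))
  gt <- genotype_table(built$genotypes, "rs174537", built$grouping)
  expect_equal(unname(gt), rbind(c(52, 38, 4), c(18, 26, 12)),
               ignore_attr = TRUE)
  expect_equal(attr(gt, "n_missing"), 0L)
  # missing calls are dropped and counted
  g2 <- built$genotypes
  g2$calls[1:5, "rs174537"] <- NA
  gt2 <- genotype_table(g2, "rs174537", built$grouping)
  expect_equal(attr(gt2, "n_missing"), 5L)
  expect_equal(sum(gt2), sum(gt) - 5L)
  expect_error(genotype_table(built$genotypes, "rs174537",
                              rep("MetS1", length(built$grouping))),
               "two levels")
  # all-homozygous toy keeps the zero heterozygote column
  toy <- toy2_geno(rbind(c(0, 0), c(2, 0), c(0, 0), c(2, 2)))
  gt3 <- genotype_table(toy, "L1", c("x", "x", "y", "y"))
  expect_equal(dim(gt3), c(2L, 3L))
  expect_equal(unname(gt3[, "Aa"]), c(0L, 0L))
})

test_that("allele tables derive from genotype counts by the 2AA + Aa rule", {
  gt <- rbind(c(52, 38, 4), c(18, 26, 12))
  expect_equal(unname(allele_table(gt)), rbind(c(142, 46), c(62, 50)))
  expect_equal(unname(allele_table(rbind(c(1, 0, 0), c(0, 0, 1)))),
               rbind(c(2, 0), c(0, 2)))
  expect_equal(rowSums(allele_table(gt)), 2 * rowSums(gt))
})

test_that("every published cluster-contrast statistic is reproduced", {
  cc <- reference_genotype_counts("mets_clusters")
  printed_geno <- c(rs174537 = 14.039, rs174570 = 10.084, rs174575 = 4.863,
                    rs174602 = 6.988, rs174589 = 5.695, rs968567 = 4.365)
  printed_allele <- c(rs174537 = 12.218, rs174570 = 8.279, rs174575 = 3.907,
                      rs174602 = 5.828, rs174589 = 4.080, rs968567 = 2.123)
  for (snp in names(printed_geno)) {
    gt <- as.matrix(cc[cc$snp == snp, c("AA", "Aa", "aa")])
    expect_equal(pearson_chi2(gt, "none")$chi2, printed_geno[[snp]],
                 tolerance = 5e-4)
    expect_equal(pearson_chi2(allele_table(gt), "yates")$chi2,
                 printed_allele[[snp]], tolerance = 5e-4)
  }
})

test_that("HWE test matches the direct formula and flags extremes", {
  res <- hwe_test(c(70, 64, 16))
  p_hat <- (2 * 70 + 64) / 300
  E <- 150 * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
  expect_equal(res$chi2, sum((c(70, 64, 16) - E)^2 / E), tolerance = 1e-12)
  expect_equal(round(res$chi2, 3), 0.058)
  expect_equal(round(res$p_raw, 2), 0.81)
  expect_equal(res$df, 1L)
  expect_equal(hwe_test(c(25, 50, 25))$chi2, 0)
  expect_lt(hwe_test(c(50, 0, 50))$p_raw, 1e-10)
  expect_warning(mono <- hwe_test(c(30, 0, 0)), "monomorphic")
  expect_equal(mono$p_raw, 1)
})

test_that("BH adjustment is the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.4, 5)), rep(0.4, 5))
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("the association scan reproduces the published contrast en bloc", {
  cc <- reference_genotype_counts("mets_clusters")
  built <- counts_to_genotypes(cc, c("MetS1", "MetS2"))
  scan <- association_scan(built$genotypes, built$grouping,
                           snps = unique(cc$snp))
  expect_equal(scan$chi2_genotype,
               c(14.039, 10.084, 4.863, 6.988, 5.695, 4.365),
               tolerance = 5e-4)
  expect_equal(scan$chi2_allele,
               c(12.218, 8.279, 3.907, 5.828, 4.080, 2.123),
               tolerance = 5e-4)
  expect_true(all(scan$p_genotype_bh >= scan$p_genotype))
  # duplicated SNP column gives identical statistics (complete LD)
  sim <- generate_cohort(default_config(n_mets = 100, n_con = 100,
                                        n_genotyped = NULL, seed = 6))
  sc <- association_scan(sim$genotypes, sim$cohort$group,
                         snps = c("rs174537", "rs174545"))
  expect_equal(sc$chi2_genotype[1], sc$chi2_genotype[2], tolerance = 1e-9)
  expect_equal(sc$chi2_allele[1], sc$chi2_allele[2], tolerance = 1e-9)
})
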