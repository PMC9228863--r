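# Synthetic cohort generator: pool structure, HWE, determinism, calibration.

test_that("default config encodes the renormalised haplotype pool", {
  cfg <- default_config()
  expect_equal(sum(cfg$haplotype_pool$freq), 1, tolerance = 1e-12)
  expect_true(all(cfg$haplotype_pool$freq >= 0))
  expect_equal(cfg$haplotype_pool$freq[cfg$haplotype_pool$core == "GGGCC"],
               0.662 / 0.990, tolerance = 1e-12)
  expect_true(all(nchar(cfg$haplotype_pool$hap) == 8L))
  # rs174545/rs174546 states are deterministic copies of rs174537
  am <- do.call(rbind, strsplit(cfg$haplotype_pool$hap, ""))
  expect_true(all((am[, 1] == "G") == (am[, 2] == "G")))
  expect_true(all((am[, 1] == "G") == (am[, 3] == "G")))
})

test_that("config validation rejects malformed pools", {
  cfg <- default_config()
  cfg$haplotype_pool$freq <- c(0.5, 0.5, 0.1, 0.1)
  expect_error(validate_config(cfg), "sum to 1")
  cfg <- default_config()
  cfg$haplotype_pool$hap[1] <- "GGGCC"
  expect_error(validate_config(cfg), "length 8")
  cfg <- default_config()
  cfg$haplotype_pool$hap[1] <- "AGGCCCTC"  # A not in rs174537's allele set
  expect_error(validate_config(cfg), "allele")
  cfg <- default_config()
  cfg$fa_params$iqr1[3] <- -1
  expect_error(validate_config(cfg), "scale")
})

test_that("haplotype pair draws follow the pool (binomial oracle)", {
  cfg <- default_config()
  cfg$haplotype_pool <- data.frame(hap = "GGGCCCTC", core = "GGGCC", freq = 1)
  cfg$cluster_logit$effects <- c(GGGCCCTC = 0)
  set.seed(1)
  pairs <- draw_haplotype_pairs(cfg, 5)
  expect_true(all(pairs == 1L))

  cfg2 <- default_config()
  cfg2$haplotype_pool <- data.frame(hap = c("GGGCCCTC", "TCATCGCC"),
                                    core = c("GGGCC", "TCATC"),
                                    freq = c(0.5, 0.5))
  cfg2$cluster_logit$effects <- c(GGGCCCTC = 0, TCATCGCC = 0)
  set.seed(7)
  pairs <- draw_haplotype_pairs(cfg2, 1e4)
  het <- mean(pairs[, 1] != pairs[, 2])
  se <- sqrt(0.5 * 0.5 / 1e4)
  expect_lt(abs(het - 0.5), 3 * se)

  set.seed(99); a <- draw_haplotype_pairs(cfg2, 100)
  set.seed(99); b <- draw_haplotype_pairs(cfg2, 100)
  expect_identical(a, b)
})

test_that("collapsing to genotypes discards phase and keeps alleles", {
  cfg <- default_config()
  pairs <- rbind(c(1L, 2L), c(2L, 2L))  # GGGCCCTC x TCATCGCC; TCATC hom
  g <- collapse_to_genotypes(pairs, cfg)
  expect_equal(unname(g$calls[1, "rs174537"]), "G/T")
  expect_equal(unname(g$calls[2, "rs174537"]), "T/T")
  expect_equal(unname(g$calls[2, "rs968567"]), "T/T")
  # full default cohort: 354 x 8, genotyped subset 330, no other missingness
  sim <- generate_cohort(default_config(seed = 2))
  expect_equal(dim(sim$genotypes$calls), c(354L, 8L))
  genotyped <- rowSums(is.na(sim$genotypes$calls)) == 0
  expect_equal(sum(genotyped), 330L)
  expect_true(all(rowSums(is.na(sim$genotypes$calls)) %in% c(0L, 8L)))
})

test_that("cluster labels follow the logistic haplotype model", {
  cfg <- default_config()
  cfg$cluster_logit$intercept <- 0
  cfg$cluster_logit$effects[] <- 0
  set.seed(3)
  pairs <- draw_haplotype_pairs(cfg, 1e4)
  lab <- assign_cluster_labels(pairs, cfg)
  expect_lt(abs(mean(lab == 1L) - 0.5), 3 * sqrt(0.25 / 1e4))

  cfg$cluster_logit$intercept <- -50  # probability-0 analogue
  expect_true(all(assign_cluster_labels(pairs, cfg) == 2L))

  # default effects enrich major-haplotype homozygotes in cluster 1 with the
  # configured odds ratio (logistic simulation oracle)
  cfg <- default_config()
  set.seed(4)
  pairs <- draw_haplotype_pairs(cfg, 2e4)
  lab <- assign_cluster_labels(pairs, cfg)
  gg <- rowSums(matrix(cfg$haplotype_pool$core[pairs] == "GGGCC",
                       ncol = 2)) == 2L
  tt <- rowSums(matrix(cfg$haplotype_pool$core[pairs] == "GGGCC",
                       ncol = 2)) == 0L
  odds <- function(x) mean(x) / (1 - mean(x))
  lor <- log(odds(lab[gg] == 1L) / odds(lab[tt] == 1L))
  expect_lt(abs(lor - 2 * 0.8), 0.25)
})

test_that("FA profiles match configured locations and directions", {
  cfg <- default_config()
  lab <- c(1L, 2L)
  X <- generate_fa_profiles(lab, cfg, noise = FALSE)
  fp <- cfg$fa_params
  expect_equal(unname(X[1, ]), fp$loc1 * sum(fp$loc1) / sum(fp$loc1),
               tolerance = 1e-9)
  expect_equal(unname(X[2, ]), fp$loc2, tolerance = 1e-9)
  set.seed(5)
  lab <- rep(1:2, each = 500)
  X <- generate_fa_profiles(lab, cfg)
  expect_equal(rowSums(X), c(sum(fp$loc1), sum(fp$loc2))[lab],
               tolerance = 1e-9)
  # linoleic acid lower in cluster 1; palmitoleic/oleic/EPA/DPA/DHA higher
  expect_lt(median(X[lab == 1, "18:2n-6"]), median(X[lab == 2, "18:2n-6"]))
  for (f in c("16:1n-7", "18:1n-9", "20:5n-3", "22:5n-3", "22:6n-3"))
    expect_gt(median(X[lab == 1, f]), median(X[lab == 2, f]))
  cfg$fa_params$iqr1[1] <- 0
  expect_error(generate_fa_profiles(1L, cfg), "scale")
})

test_that("cohort generation is deterministic and respects group forcing", {
  a <- generate_cohort(default_config(seed = 42))
  b <- generate_cohort(default_config(seed = 42))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$truth$hap1, b$truth$hap1)

  con_only <- generate_cohort(default_config(n_mets = 0L, n_con = 40L,
                                             n_genotyped = NULL, seed = 1))
  expect_true(all(con_only$cohort$group == "CON"))
  expect_equal(nrow(con_only$cohort), 40L)
})

test_that("unphased genotype pairs collapse exactly to the truth record", {
  sim <- generate_cohort(default_config(n_mets = 40, n_con = 40,
                                        n_genotyped = NULL, seed = 8))
  a1 <- do.call(rbind, strsplit(sim$truth$hap1, ""))
  a2 <- do.call(rbind, strsplit(sim$truth$hap2, ""))
  rebuilt <- matrix(paste(pmin(a1, a2), pmax(a1, a2), sep = "/"),
                    nrow = nrow(a1))
  expect_equal(unname(sim$genotypes$calls), rebuilt)
})

test_that("generated genotypes sit in Hardy-Weinberg equilibrium", {
  # rejection rate of the 5% HWE test across replicate cohorts is ~5%
  set.seed(11)
  seeds <- sample.int(1e6, 60)
  rej <- vapply(seeds, function(s) {
    sim <- generate_cohort(default_config(n_mets = 250, n_con = 250,
                                          n_genotyped = NULL, seed = s))
    dos <- geno_dosage(sim$genotypes)[, "rs174537"]
    hwe_test(c(sum(dos == 0), sum(dos == 1), sum(dos == 2)))$p_raw < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 60) + 0.01)
})

test_that("construction puts rs174537 and rs174545 in complete LD", {
  sim <- generate_cohort(default_config(n_mets = 300, n_con = 300,
                                        n_genotyped = NULL, seed = 13))
  ld <- pairwise_ld(sim$genotypes, "rs174537", "rs174545")
  expect_equal(ld$r2, 1, tolerance = 1e-9)
  expect_equal(ld$d_prime, 1, tolerance = 1e-9)
})
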