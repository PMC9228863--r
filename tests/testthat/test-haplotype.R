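# EM haplotype frequencies, LD measures, block partition, phasing and the
# permutation-corrected haplotype association.

test_that("EM resolves trivial and coupling-biased toy instances", {
  # single double-homozygote: one haplotype at frequency 1
  hs <- em_haplotype_frequencies(toy2_geno(rbind(c(0, 0))), c("L1", "L2"))
  expect_equal(hs$haplotypes$freq[1], 1)
  expect_equal(hs$haplotypes$hap[1], "GC")
  # one GC/GC homozygote + one double heterozygote: MLE puts 3/4 on the
  # coupling haplotype (maximise 3 log f + log(1 - f))
  hs2 <- em_haplotype_frequencies(toy2_geno(rbind(c(0, 0), c(1, 1))),
                                  c("L1", "L2"), tol = 1e-10)
  f_gc <- hs2$haplotypes$freq[hs2$haplotypes$hap == "GC"]
  f_tt <- hs2$haplotypes$freq[hs2$haplotypes$hap == "TT"]
  expect_equal(f_gc, 0.75, tolerance = 1e-3)
  expect_equal(f_tt, 0.25, tolerance = 1e-3)
  expect_true(hs2$converged)
})

test_that("EM log-likelihood is non-decreasing and matches the grid oracle", {
  set.seed(1)
  for (i in 1:12) {
    n <- sample(2:6, 1)
    dos <- cbind(sample(0:2, n, replace = TRUE),
                 sample(0:2, n, replace = TRUE))
    hs <- em_haplotype_frequencies(toy2_geno(dos), c("L1", "L2"),
                                   tol = 1e-10, restarts = 4L)
    expect_true(all(diff(hs$loglik_trace) > -1e-9))
    # oracle: brute-force likelihood grid over the haplotype simplex
    grid <- grid_max_2locus(dos, step = 0.01)
    expect_gte(hs$loglik, grid$loglik - 1e-3)
    # the EM frequencies themselves score at the EM log-likelihood under the
    # independent likelihood evaluator
    f <- setNames(hs$haplotypes$freq, hs$haplotypes$hap)
    fvec <- unname(f[c("GC", "GT", "TC", "TT")])
    fvec[is.na(fvec)] <- 0
    expect_equal(loglik_2locus(dos, fvec), hs$loglik, tolerance = 1e-6)
  }
})

test_that("EM recovers the generator pool frequencies at n = 2000", {
  cfg <- default_config(n_mets = 1000, n_con = 1000, n_genotyped = NULL,
                        seed = 5)
  sim <- generate_cohort(cfg)
  hs <- em_haplotype_frequencies(sim$genotypes, fads_block_loci())
  est <- setNames(hs$haplotypes$freq, hs$haplotypes$hap)
  truth <- setNames(cfg$haplotype_pool$freq, cfg$haplotype_pool$core)
  for (h in names(truth))
    expect_lt(abs(est[[h]] - truth[[h]]), 0.02)
  expect_true(hs$converged)
  expect_equal(sum(hs$haplotypes$freq), 1, tolerance = 1e-8)
})

test_that("LD measures match hand-computed two-locus frequencies", {
  # unambiguous phase: 5x GC/GC, 1x GT/GT, 1x TC/TC, 3x TT/TT gives
  # chromosome counts 10/2/2/6, so f(GC)=0.5, f(G.)=0.6, f(.C)=0.6
  dos <- rbind(matrix(0, 5, 2), c(0, 2), c(2, 0),
               matrix(2, 3, 2))
  ld <- pairwise_ld(toy2_geno(dos), "L1", "L2")
  D <- 0.5 - 0.6 * 0.6
  expect_equal(ld$D, D, tolerance = 1e-6)
  expect_equal(ld$d_prime, D / min(0.6 * 0.4, 0.4 * 0.6), tolerance = 1e-6)
  expect_equal(ld$r2, D^2 / (0.6 * 0.4 * 0.6 * 0.4), tolerance = 1e-6)
  # independent loci: D ~ 0; perfect coupling: D' = r2 = 1
  dos_ind <- as.matrix(expand.grid(0:2, 0:2))[rep(1:9, c(1,2,1,2,4,2,1,2,1)), ]
  ld0 <- pairwise_ld(toy2_geno(dos_ind), "L1", "L2")
  expect_lt(abs(ld0$D), 1e-6)
  expect_lt(ld0$r2, 1e-6)
  dos_coup <- rbind(matrix(0, 5, 2), matrix(1, 5, 2), matrix(2, 5, 2))
  ldc <- pairwise_ld(toy2_geno(dos_coup), "L1", "L2")
  expect_equal(ldc$d_prime, 1, tolerance = 1e-6)
  expect_equal(ldc$r2, 1, tolerance = 1e-6)
  expect_warning(pairwise_ld(toy2_geno(rbind(c(0, 0), c(0, 2))), "L1", "L2"),
                 "monomorphic")
})

test_that("LD matrices are symmetric, bounded, and r2 = 1 implies D' = 1", {
  sim <- generate_cohort(default_config(n_mets = 150, n_con = 150,
                                        n_genotyped = NULL, seed = 7))
  ld <- ld_matrix(sim$genotypes)
  expect_true(all(ld$r2 >= 0 & ld$r2 <= 1 + 1e-9))
  expect_true(all(ld$d_prime >= 0 & ld$d_prime <= 1 + 1e-9))
  expect_equal(ld$r2, t(ld$r2))
  expect_equal(ld$d_prime, t(ld$d_prime))
  near1 <- which(ld$r2 > 1 - 1e-9, arr.ind = TRUE)
  expect_true(all(ld$d_prime[near1] > 1 - 1e-9))
  expect_equal(ld$r2["rs174537", "rs174545"], 1, tolerance = 1e-9)
})

test_that("block partition finds contiguous high-D' runs", {
  loci <- paste0("s", 1:4)
  dp1 <- matrix(1, 4, 4, dimnames = list(loci, loci))
  expect_equal(block_partition(dp1), list(loci))
  dp0 <- diag(4); dimnames(dp0) <- list(loci, loci)
  expect_equal(block_partition(dp0), list())
  # synthetic default cohort: the FADS1 trio sits in one block
  sim <- generate_cohort(default_config(n_mets = 150, n_con = 150,
                                        n_genotyped = NULL, seed = 9))
  blocks <- block_partition(ld_matrix(sim$genotypes), 0.8)
  hit <- vapply(blocks, function(b)
    all(c("rs174537", "rs174545", "rs174546") %in% b), TRUE)
  expect_true(any(hit))
})

test_that("phase assignment maximises the pair posterior with tie-breaks", {
  sim <- generate_cohort(default_config(n_mets = 200, n_con = 200,
                                        n_genotyped = NULL, seed = 10))
  hs <- em_haplotype_frequencies(sim$genotypes, fads_block_loci())
  # double homozygote: unique pair, posterior 1
  hom <- setNames(rep("C/C", 5), fads_block_loci())
  hom[1:3] <- c("G/G", "G/G", "G/G")
  ph <- assign_phase(hs, hom)
  expect_equal(ph$posterior, 1)
  expect_equal(ph$hap1, "GGGCC")
  # full double heterozygote: coupling pair wins; posterior equals the
  # two-haplotype Bayes ratio computed by hand from the EM frequencies
  het <- setNames(c("G/T", "C/G", "A/G", "C/T", "C/T"), fads_block_loci())
  ph2 <- assign_phase(hs, het)
  f <- setNames(hs$haplotypes$freq, hs$haplotypes$hap)
  pairs <- expand.grid(h1 = names(f), h2 = names(f),
                       stringsAsFactors = FALSE)
  compatible <- function(h1, h2)
    all(vapply(1:5, function(l) {
      al <- sort(c(substring(h1, l, l), substring(h2, l, l)))
      paste(al, collapse = "/") == het[l]
    }, TRUE))
  w <- mapply(function(h1, h2)
    if (compatible(h1, h2)) f[[h1]] * f[[h2]] * (2 - (h1 == h2)) else 0,
    pairs$h1, pairs$h2)
  expect_equal(ph2$posterior, max(w) / (sum(w) / 2), tolerance = 1e-9)
  # symmetric frequencies: deterministic lexicographic tie-break
  flat <- hs
  flat$haplotypes <- data.frame(hap = c("GC", "GT", "TC", "TT"),
                                freq = rep(0.25, 4),
                                above_floor = TRUE)
  flat$loci <- c("L1", "L2")
  ph3 <- assign_phase(flat, setNames(c("G/T", "C/T"), c("L1", "L2")))
  expect_equal(ph3$posterior, 0.5)
  expect_equal(c(ph3$hap1, ph3$hap2), c("GC", "TT"))
})

test_that("haplotype association is seed-stable with valid permutation p", {
  sim <- generate_cohort(default_config(n_mets = 150, n_con = 150,
                                        n_genotyped = NULL, seed = 12))
  grp <- sim$cohort$group
  a <- haplotype_association(sim$genotypes, grp, fads_block_loci(),
                             n_perm = 99, seed = 4)
  b <- haplotype_association(sim$genotypes, grp, fads_block_loci(),
                             n_perm = 99, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$p_perm_corrected >= a$p_perm_raw))
  expect_true(all(a$p_perm_corrected >= 1 / 100 &
                  a$p_perm_corrected <= 1))
  expect_true(all(a$freq_pooled >= 0.01))
  # perfect association: grouping = carrier status of the top haplotype
  dos <- geno_dosage(sim$genotypes)[, "rs174537"]
  carrier <- ifelse(dos == 2, "hom", "other")  # GGGCC homozygote indicator
  perf <- haplotype_association(sim$genotypes, carrier, fads_block_loci(),
                                n_perm = 199, seed = 4)
  expect_equal(min(perf$p_perm_corrected), 1 / 200, tolerance = 1e-12)
  # the two permutation engines agree on the observed statistics
  d <- haplotype_association(sim$genotypes, grp, fads_block_loci(),
                             n_perm = 99, seed = 4, method = "dosage")
  expect_equal(d$chi2, a$chi2, tolerance = 0.5)
  expect_gt(cor(d$chi2, a$chi2), 0.95)
})
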