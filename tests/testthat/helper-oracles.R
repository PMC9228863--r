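# Independent oracles and small fixture builders used across the suite.

# plain Rand index: fraction of subject pairs on which two partitions agree
rand_index <- function(a, b) {
  n <- length(a)
  (sum(outer(a, a, "==") == outer(b, b, "==")) - n) / (n * (n - 1))
}

# Exhaustive Ward oracle: at every step recompute the delta-SS of every
# candidate merge directly from the data (no recurrence) and take the best,
# breaking ties like the implementation (smallest min-leaf pair).
ward_oracle <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  clusters <- lapply(seq_len(n), identity)
  ss <- function(idx) {
    M <- X[idx, , drop = FALSE]
    sum(sweep(M, 2, colMeans(M))^2)
  }
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- ss(c(clusters[[i]], clusters[[j]])) - ss(clusters[[i]]) - ss(clusters[[j]])
      key <- c(d, min(clusters[[i]], clusters[[j]]),
               max(min(clusters[[i]]), min(clusters[[j]])))
      if (is.null(best) ||
          d < best$key[1] - 1e-9 ||
          (abs(d - best$key[1]) <= 1e-9 &&
           (key[2] < best$key[2] ||
            (key[2] == best$key[2] && key[3] < best$key[3])))) {
        best <- list(i = i, j = j, key = key)
      }
    }
    heights[s] <- best$key[1]
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  heights
}

# Exhaustive Ward partition at k clusters (same greedy delta-SS rule).
ward_oracle_cut <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  clusters <- lapply(seq_len(n), identity)
  ss <- function(idx) {
    M <- X[idx, , drop = FALSE]
    sum(sweep(M, 2, colMeans(M))^2)
  }
  while (length(clusters) > k) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- ss(c(clusters[[i]], clusters[[j]])) - ss(clusters[[i]]) - ss(clusters[[j]])
      if (is.null(best) || d < best$d - 1e-9) best <- list(i = i, j = j, d = d)
    }
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  lab <- integer(n)
  for (c0 in seq_along(clusters)) lab[clusters[[c0]]] <- c0
  lab
}

# Two-locus haplotype likelihood machinery, independent of the package EM.
# Subjects are given as minor-allele dosage pairs (d1, d2) in {0,1,2}^2.
# Haplotype order: AB, Ab, aB, ab (minor-allele indicators 00, 01, 10, 11).
hap2_minor <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))

loglik_2locus <- function(dosages, f) {
  ll <- 0
  for (r in seq_len(nrow(dosages))) {
    p <- 0
    for (i in 1:4) for (j in 1:4) {
      if (all(hap2_minor[i, ] + hap2_minor[j, ] == dosages[r, ]))
        p <- p + f[i] * f[j]
    }
    ll <- ll + log(max(p, 1e-300))
  }
  ll
}

# Brute-force grid maximisation of the two-locus haplotype likelihood
# (step over the 3-simplex); returns the best log-likelihood and frequencies.
grid_max_2locus <- function(dosages, step = 0.005) {
  g <- seq(0, 1, by = step)
  best_ll <- -Inf
  best_f <- NULL
  # vectorise over f1 for each (f2, f3) pair
  for (f2 in g) for (f3 in g) {
    if (f2 + f3 > 1) next
    f1 <- g[g <= 1 - f2 - f3 + 1e-12]
    f4 <- 1 - f2 - f3 - f1
    ll <- numeric(length(f1))
    for (r in seq_len(nrow(dosages))) {
      p <- numeric(length(f1))
      fmat <- cbind(f1, f2, f3, f4)
      for (i in 1:4) for (j in i:4) {
        if (all(hap2_minor[i, ] + hap2_minor[j, ] == dosages[r, ]))
          p <- p + fmat[, i] * fmat[, j] * if (i == j) 1 else 2
      }
      ll <- ll + log(pmax(p, 1e-300))
    }
    w <- which.max(ll)
    if (ll[w] > best_ll) {
      best_ll <- ll[w]
      best_f <- c(f1[w], f2, f3, 1 - f2 - f3 - f1[w])
    }
  }
  list(loglik = best_ll, freq = best_f)
}

# Build a genotype_matrix for two toy loci (alleles G/T and C/T) from
# minor-allele dosage pairs.
toy2_geno <- function(dosages) {
  snps <- data.frame(snp = c("L1", "L2"), chrom = "1", pos = c(100L, 200L),
                     major = c("G", "C"), minor = c("T", "T"),
                     gene = NA_character_, stringsAsFactors = FALSE)
  cls <- list(c("G/G", "G/T", "T/T"), c("C/C", "C/T", "T/T"))
  calls <- cbind(cls[[1]][dosages[, 1] + 1L], cls[[2]][dosages[, 2] + 1L])
  genotype_matrix(calls, snps)
}

# Expand per-stratum (AA, Aa, aa) counts for the FADS panel into a
# genotype_matrix plus stratum labels (deterministic subject order).
counts_to_genotypes <- function(counts, strata) {
  panel <- fads_snp_panel()
  n_per <- vapply(strata, function(s) {
    sum(counts[counts$stratum == s & counts$snp == counts$snp[1],
               c("AA", "Aa", "aa")])
  }, 0)
  grouping <- rep(strata, n_per)
  calls <- NULL
  for (snp in unique(counts$snp)) {
    meta <- panel[panel$snp == snp, ]
    cls <- c(paste(sort(c(meta$major, meta$major)), collapse = "/"),
             paste(sort(c(meta$major, meta$minor)), collapse = "/"),
             paste(sort(c(meta$minor, meta$minor)), collapse = "/"))
    col <- unlist(lapply(strata, function(s) {
      k <- counts[counts$stratum == s & counts$snp == snp, c("AA", "Aa", "aa")]
      rep(cls, times = as.integer(k))
    }))
    calls <- cbind(calls, col)
  }
  snps <- panel[match(unique(counts$snp), panel$snp), ]
  list(genotypes = genotype_matrix(calls, snps), grouping = grouping)
}

# a null generator config: haplotypes carry no cluster effect
null_generator_config <- function(seed, n_mets = 200L, n_con = 200L) {
  cfg <- default_config(n_mets = n_mets, n_con = n_con, n_genotyped = NULL,
                        seed = seed)
  cfg$cluster_logit$effects[] <- 0
  cfg
}
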