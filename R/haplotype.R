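# EM estimation of multi-locus haplotype frequencies from unphased
# genotypes (Excoffier-Slatkin style), pairwise linkage disequilibrium
# (D, D', r^2), contiguous D'-threshold block partitioning, per-subject
# phase assignment, and haplotype-cluster association with max-statistic
# permutation correction.

# ---- internal machinery ----------------------------------------------------

# enumerate all haplotype pairs compatible with one subject's unphased
# genotype; a1/a2 are per-locus allele character vectors. The first
# heterozygous locus is fixed to break the pair symmetry.
enum_pairs <- function(a1, a2) {
  het <- which(a1 != a2)
  if (!length(het))
    return(matrix(c(paste(a1, collapse = ""), paste(a2, collapse = "")), 1, 2))
  rest <- het[-1]
  m <- length(rest)
  n_cfg <- 2L^m
  out <- matrix("", n_cfg, 2L)
  for (r in seq_len(n_cfg)) {
    bits <- as.logical(bitwAnd(r - 1L, as.integer(2^(seq_len(m) - 1L))))
    h1 <- a1; h2 <- a2
    flip <- rest[bits]
    h1[flip] <- a2[flip]; h2[flip] <- a1[flip]
    out[r, ] <- c(paste(h1, collapse = ""), paste(h2, collapse = ""))
  }
  out
}

# flatten the genotype calls at `loci` into the EM data structure:
# integer vectors (subj, a, b) over all compatible pairs plus the haplotype
# string table. Subjects incomplete on the loci are excluded.
build_em_structure <- function(genotypes, loci) {
  j <- match(loci, genotypes$snps$snp)
  if (anyNA(j)) stop("unknown locus: ", loci[which(is.na(j))[1]])
  if (length(loci) > 12L) stop("more than 12 loci: enumeration infeasible")
  calls <- genotypes$calls[, j, drop = FALSE]
  complete <- !apply(is.na(calls), 1L, any)
  n_dropped <- sum(!complete)
  calls <- calls[complete, , drop = FALSE]
  if (nrow(calls) == 0L) stop("no subject with complete data on the loci")
  a1 <- matrix(substring(calls, 1L, 1L), nrow(calls))
  a2 <- matrix(substring(calls, 3L, 3L), nrow(calls))
  subj <- integer(0); h1 <- character(0); h2 <- character(0)
  pieces <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    pr <- enum_pairs(a1[i, ], a2[i, ])
    pieces[[i]] <- cbind(i, pr)
  }
  flat <- do.call(rbind, pieces)
  haps <- sort(unique(c(flat[, 2], flat[, 3])))
  list(subj = as.integer(flat[, 1]),
       a = match(flat[, 2], haps), b = match(flat[, 3], haps),
       haps = haps, n = nrow(calls), n_dropped = n_dropped,
       ids = rownames(calls),
       allele1 = a1, allele2 = a2)
}

# restrict an EM structure to a candidate haplotype list; subjects with no
# remaining compatible pair are dropped (counted).
restrict_structure <- function(st, candidates) {
  keep_h <- st$haps %in% candidates
  keep <- keep_h[st$a] & keep_h[st$b]
  subj_kept <- sort(unique(st$subj[keep]))
  lost <- st$n - length(subj_kept)
  remap_s <- match(st$subj[keep], subj_kept)
  haps <- st$haps[keep_h]
  list(subj = remap_s,
       a = match(st$haps[st$a[keep]], haps),
       b = match(st$haps[st$b[keep]], haps),
       haps = haps, n = length(subj_kept),
       n_dropped = st$n_dropped + lost,
       ids = st$ids[subj_kept],
       subj_orig = subj_kept)
}

# one EM run on a prebuilt structure; returns frequencies, loglik trace,
# convergence flag.
em_run <- function(st, init, tol = 1e-6, max_iter = 1000L) {
  H <- length(st$haps)
  f <- init / sum(init)
  same <- st$a == st$b
  mult <- ifelse(same, 1, 2)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    w <- f[st$a] * f[st$b] * mult
    tot <- rowsum(w, st$subj)          # ordered by subject index
    trace <- c(trace, sum(log(pmax(tot, 1e-300))))
    post <- w / pmax(tot[st$subj], 1e-300)
    nh <- numeric(H)
    acc <- rowsum(c(post, post), c(st$a, st$b))
    nh[as.integer(rownames(acc))] <- acc
    f_new <- nh / (2 * st$n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # loglik at the final frequencies
  w <- f[st$a] * f[st$b] * mult
  trace <- c(trace, sum(log(pmax(rowsum(w, st$subj), 1e-300))))
  list(freq = f, loglik = trace[length(trace)], loglik_trace = trace,
       iterations = it, converged = converged)
}

marginal_init <- function(st) {
  L <- nchar(st$haps[1])
  am <- do.call(rbind, strsplit(st$haps, ""))
  # observed allele frequencies per locus from the genotype calls
  f <- rep(1, length(st$haps))
  for (l in seq_len(L)) {
    obs <- c(st$allele1[, l], st$allele2[, l])
    tab <- table(obs) / length(obs)
    f <- f * as.numeric(tab[am[, l]])
  }
  f[is.na(f) | f <= 0] <- 1e-12
  f / sum(f)
}

# ---- exported operations ---------------------------------------------------

#' EM haplotype frequency estimation from unphased genotypes
#'
#' Standard multilocus EM: the E-step distributes each ambiguous genotype
#' over its compatible haplotype pairs proportional to the current pair
#' probabilities (2 f_a f_b for a != b, f_a^2 otherwise); the M-step
#' re-estimates frequencies from the expected pair counts. Iteration stops
#' when the largest frequency change drops below `tol` or at `max_iter`
#' (then `converged = FALSE`, result still returned). Initialisation is the
#' product of observed allele marginals; additional random restarts guard
#' against local maxima and the best log-likelihood is kept. Subjects
#' incomplete on the requested loci are excluded (count recorded).
#'
#' @param genotypes A `genotype_matrix`.
#' @param loci SNP ids (<= 12).
#' @param tol Convergence tolerance on the max frequency change.
#' @param max_iter Maximum EM iterations.
#' @param restarts Total initialisations (1 = marginal product only).
#' @param floor Reporting floor: haplotypes at or above it are flagged
#'   `above_floor` (all are retained).
#' @return An object of class `haplotype_set`: list with `loci`,
#'   `haplotypes` (data.frame: hap, freq, above_floor), `loglik`,
#'   `loglik_trace`, `iterations`, `converged`, `n_subjects`, `n_dropped`.
#' @export
em_haplotype_frequencies <- function(genotypes, loci, tol = 1e-6,
                                     max_iter = 1000L, restarts = 3L,
                                     floor = 0.01) {
  st <- build_em_structure(genotypes, loci)
  best <- em_run(st, marginal_init(st), tol, max_iter)
  if (restarts > 1L) for (r in seq_len(restarts - 1L)) {
    init <- stats::rgamma(length(st$haps), 1)
    cand <- em_run(st, init, tol, max_iter)
    if (cand$loglik > best$loglik + 1e-9) best <- cand
  }
  hs <- data.frame(hap = st$haps, freq = best$freq,
                   above_floor = best$freq >= floor,
                   stringsAsFactors = FALSE)
  hs <- hs[order(-hs$freq), ]
  rownames(hs) <- NULL
  structure(list(loci = loci, haplotypes = hs, loglik = best$loglik,
                 loglik_trace = best$loglik_trace,
                 iterations = best$iterations, converged = best$converged,
                 n_subjects = st$n, n_dropped = st$n_dropped),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set over", paste(x$loci, collapse = "-"), "\n")
  print(x$haplotypes[x$haplotypes$above_floor, c("hap", "freq")],
        row.names = FALSE)
  cat(sprintf("logLik %.3f after %d iterations (%s), n = %d (%d dropped)\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged",
              x$n_subjects, x$n_dropped))
  invisible(x)
}

ld_from_freqs <- function(fAB, fA, fB) {
  D <- fAB - fA * fB
  denom <- fA * (1 - fA) * fB * (1 - fB)
  if (denom <= 0) return(list(D = NA_real_, d_prime = NA_real_, r2 = NA_real_))
  dmax <- if (D > 0) min(fA * (1 - fB), (1 - fA) * fB)
          else min(fA * fB, (1 - fA) * (1 - fB))
  list(D = D,
       d_prime = if (D == 0) 0 else abs(D) / dmax,
       r2 = D^2 / denom)
}

#' Pairwise linkage disequilibrium between two SNPs
#'
#' Two-locus haplotype frequencies are estimated by EM, then
#' D = f(AB) - f(A) f(B) (A, B the major alleles),
#' D' = |D| / Dmax with Dmax = min(f(A) f(b), f(a) f(B)) for D > 0 and
#' min(f(A) f(B), f(a) f(b)) otherwise, and
#' r^2 = D^2 / (f(A) f(a) f(B) f(b)). A monomorphic locus gives NA with a
#' warning.
#'
#' @param genotypes A `genotype_matrix`.
#' @param snp_i,snp_j SNP ids.
#' @return List of class `ld_pair`: `snp_i`, `snp_j`, `D`, `d_prime`, `r2`.
#' @export
pairwise_ld <- function(genotypes, snp_i, snp_j) {
  hs <- em_haplotype_frequencies(genotypes, c(snp_i, snp_j), restarts = 1L)
  meta <- genotypes$snps
  A <- meta$major[match(snp_i, meta$snp)]
  B <- meta$major[match(snp_j, meta$snp)]
  h <- hs$haplotypes
  fA <- sum(h$freq[substring(h$hap, 1, 1) == A])
  fB <- sum(h$freq[substring(h$hap, 2, 2) == B])
  fAB <- sum(h$freq[substring(h$hap, 1, 1) == A & substring(h$hap, 2, 2) == B])
  ld <- ld_from_freqs(fAB, fA, fB)
  if (is.na(ld$r2)) warning("monomorphic locus: LD undefined for ",
                            snp_i, "/", snp_j)
  structure(c(list(snp_i = snp_i, snp_j = snp_j), ld), class = "ld_pair")
}

#' Pairwise LD matrices over a set of loci
#'
#' @param genotypes A `genotype_matrix`.
#' @param loci SNP ids in map order (default: all).
#' @return List with symmetric matrices `d_prime` and `r2` (diagonal 1) and
#'   the locus vector.
#' @export
ld_matrix <- function(genotypes, loci = genotypes$snps$snp) {
  L <- length(loci)
  dp <- r2 <- matrix(1, L, L, dimnames = list(loci, loci))
  for (i in seq_len(L - 1L)) for (j in seq((i + 1L), L)) {
    ld <- suppressWarnings(pairwise_ld(genotypes, loci[i], loci[j]))
    dp[i, j] <- dp[j, i] <- ld$d_prime
    r2[i, j] <- r2[j, i] <- ld$r2
  }
  list(d_prime = dp, r2 = r2, loci = loci)
}

#' Contiguous haplotype block partition by D' threshold
#'
#' Greedy maximal contiguous runs of loci in which every within-run pair has
#' D' >= `threshold`. A documented substitute for likelihood-based block
#' finding: blocks of a single locus are not reported.
#'
#' @param ld An object from [ld_matrix()] (or a D' matrix with locus
#'   dimnames).
#' @param threshold Minimum within-block pairwise D' (default 0.8).
#' @return List of character vectors (member loci per block), possibly empty.
#' @export
block_partition <- function(ld, threshold = 0.8) {
  dp <- if (is.list(ld)) ld$d_prime else ld
  loci <- colnames(dp)
  L <- length(loci)
  blocks <- list()
  i <- 1L
  while (i < L) {
    j <- i
    repeat {
      if (j >= L) break
      nxt <- dp[i:j, j + 1L]
      if (anyNA(nxt) || any(nxt < threshold)) break
      j <- j + 1L
    }
    if (j > i) blocks[[length(blocks) + 1L]] <- loci[i:j]
    i <- j + 1L
  }
  blocks
}

#' Most probable haplotype pair for one subject
#'
#' Argmax over the pairs compatible with the subject's unphased genotype of
#' f_a f_b (2 - [a = b]) under the supplied haplotype frequencies; posterior
#' reported. If no compatible pair has positive probability the posterior
#' falls back to uniform over compatible pairs (flagged). Ties break
#' lexicographically.
#'
#' @param hapset A `haplotype_set`.
#' @param subject_genotype Named character vector of calls (`"X/Y"`) for the
#'   hapset's loci, or a 1-row slice of `genotype_matrix` calls.
#' @return List: `hap1`, `hap2`, `posterior`, `fallback_uniform`.
#' @export
assign_phase <- function(hapset, subject_genotype) {
  calls <- subject_genotype[hapset$loci]
  if (anyNA(calls)) stop("subject incomplete on the hapset loci")
  pr <- enum_pairs(substring(calls, 1, 1), substring(calls, 3, 3))
  f <- setNames(hapset$haplotypes$freq, hapset$haplotypes$hap)
  fa <- unname(f[pr[, 1]]); fb <- unname(f[pr[, 2]])
  fa[is.na(fa)] <- 0; fb[is.na(fb)] <- 0
  w <- fa * fb * ifelse(pr[, 1] == pr[, 2], 1, 2)
  fallback <- sum(w) == 0
  if (fallback) w <- rep(1, length(w))
  post <- w / sum(w)
  h1 <- pmin(pr[, 1], pr[, 2]); h2 <- pmax(pr[, 1], pr[, 2])
  ord <- order(-post, h1, h2)
  best <- ord[1]
  list(hap1 = h1[best], hap2 = h2[best], posterior = post[best],
       fallback_uniform = fallback)
}

# Pearson chi2 of a haplotype-vs-rest 2x2 with (possibly fractional)
# expected counts c1/c2 out of totals t1/t2 chromosomes.
hap_chi2 <- function(c1, c2, t1, t2) {
  O <- rbind(c(c1, t1 - c1), c(c2, t2 - c2))
  O <- round(O, 2)
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs <= 0) || any(cs <= 0)) return(0)
  E <- outer(rs, cs) / sum(O)
  sum((O - E)^2 / E)
}

#' Haplotype-phenotype association with max-statistic permutation correction
#'
#' Pools the two groups for an EM support estimate, computes per-group
#' expected haplotype counts, and tests each haplotype (this haplotype vs all
#' others, by group) with a Pearson chi-squared on the expected counts
#' (rounded to 0.01). Family-wise corrected p-values come from label
#' permutations: corrected p = (1 + #\{permutation max statistic >= observed
#' statistic\}) / (n_perm + 1).
#'
#' Two permutation engines: `method = "em"` re-estimates per-group
#' frequencies by EM (restricted to the pooled support) for every permuted
#' labelling; `method = "dosage"` freezes each subject's expected haplotype
#' dosages at the pooled estimate and only re-aggregates them, which is much
#' faster and is intended for large simulation studies.
#'
#' @param genotypes A `genotype_matrix`.
#' @param grouping Two-level grouping, one entry per subject (aligned with
#'   the genotype rows).
#' @param loci Loci defining the haplotypes.
#' @param n_perm Number of label permutations (>= 1).
#' @param seed Optional integer seed for the permutations.
#' @param method `"em"` or `"dosage"` (see above).
#' @param floor Haplotypes with pooled frequency below this are not tested.
#' @param tol,max_iter EM settings for the per-permutation refits.
#' @return data.frame: `hap`, `freq_pooled`, `freq_g1`, `freq_g2`, `chi2`,
#'   `p_perm_raw`, `p_perm_corrected`; attributes `groups`, `n_perm`,
#'   `method`.
#' @export
haplotype_association <- function(genotypes, grouping, loci,
                                  n_perm = 1000L, seed = NULL,
                                  method = c("em", "dosage"),
                                  floor = 0.01, tol = 1e-5,
                                  max_iter = 200L) {
  method <- match.arg(method)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  st <- build_em_structure(genotypes, loci)
  g_all <- factor(grouping)
  if (nlevels(g_all) != 2L) stop("grouping must have two levels")
  # align grouping with the complete subjects kept in the structure
  keep_ids <- st$ids
  g <- g_all[match(keep_ids, rownames(genotypes$calls))]
  if (anyNA(g) || min(table(g)) < 2L) stop("degenerate group sizes")

  pooled <- em_run(st, marginal_init(st), tol = 1e-6, max_iter = 1000L)
  support <- st$haps[pooled$freq > 1e-6]
  stR <- restrict_structure(st, support)
  gR <- g[stR$subj_orig]
  pooledR <- em_run(stR, rep(1, length(stR$haps)), tol = 1e-6,
                    max_iter = 1000L)

  lev <- levels(gR)
  n1 <- sum(gR == lev[1]); n2 <- sum(gR == lev[2])
  H <- length(stR$haps)

  group_freqs_em <- function(gv) {
    f <- matrix(0, 2, H)
    for (k in 1:2) {
      rows <- which(gv[stR$subj] == lev[k])
      sub <- list(subj = match(stR$subj[rows], sort(unique(stR$subj[rows]))),
                  a = stR$a[rows], b = stR$b[rows], haps = stR$haps,
                  n = length(unique(stR$subj[rows])))
      f[k, ] <- em_run(sub, pooledR$freq, tol, max_iter)$freq
    }
    f
  }

  dosage <- NULL
  if (method == "dosage") {
    w <- pooledR$freq[stR$a] * pooledR$freq[stR$b] *
      ifelse(stR$a == stR$b, 1, 2)
    tot <- rowsum(w, stR$subj)
    post <- w / pmax(tot[stR$subj], 1e-300)
    dosage <- matrix(0, stR$n, H)
    for (col in 1:2) {
      idx <- if (col == 1) stR$a else stR$b
      inc <- rowsum(post, group = (stR$subj - 1L) * H + idx)
      pos <- as.integer(rownames(inc))
      dosage[cbind((pos - 1L) %/% H + 1L, (pos - 1L) %% H + 1L)] <-
        dosage[cbind((pos - 1L) %/% H + 1L, (pos - 1L) %% H + 1L)] + inc
    }
  }

  stat_vector <- function(gv) {
    if (method == "em") {
      f <- group_freqs_em(gv)
      c1 <- 2 * sum(gv == lev[1]) * f[1, ]
      c2 <- 2 * sum(gv == lev[2]) * f[2, ]
    } else {
      c1 <- colSums(dosage[gv == lev[1], , drop = FALSE])
      c2 <- colSums(dosage[gv == lev[2], , drop = FALSE])
    }
    t1 <- sum(c1); t2 <- sum(c2)
    vapply(seq_len(H), function(h) hap_chi2(c1[h], c2[h], t1, t2), 0)
  }

  obs_f <- group_freqs_em(gR)
  test_idx <- which(pooledR$freq >= floor)
  obs_stat <- stat_vector(gR)

  exceed_max <- numeric(H)
  exceed_raw <- numeric(H)
  for (p in seq_len(n_perm)) {
    gp <- sample(gR)
    sp <- stat_vector(gp)
    mx <- max(sp[test_idx])
    exceed_max <- exceed_max + (mx >= obs_stat - 1e-12)
    exceed_raw <- exceed_raw + (sp >= obs_stat - 1e-12)
  }
  out <- data.frame(
    hap = stR$haps[test_idx],
    freq_pooled = pooledR$freq[test_idx],
    freq_g1 = obs_f[1, test_idx],
    freq_g2 = obs_f[2, test_idx],
    chi2 = obs_stat[test_idx],
    p_perm_raw = (1 + exceed_raw[test_idx]) / (n_perm + 1),
    p_perm_corrected = (1 + exceed_max[test_idx]) / (n_perm + 1),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$freq_pooled), ]
  rownames(out) <- NULL
  attr(out, "groups") <- lev
  attr(out, "n_perm") <- n_perm
  attr(out, "method") <- method
  out
}
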