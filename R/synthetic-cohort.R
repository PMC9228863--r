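# Synthetic cohort generator: haplotype-structured genotypes, cluster-
# dependent fatty acid profiles and clinical covariates. The defaults encode
# the study conditions the analysis pipeline assumes: a five-SNP haplotype
# block with frequencies 66.2/14.9/13.0/4.9% (renormalised to sum 1),
# complete LD among the three FADS1 SNPs (alleles copied), Hardy-Weinberg
# genotypes via random mating, and haplotype-dependent cluster membership.

#' Default generator configuration
#'
#' Builds the configuration for [generate_cohort()]. The haplotype pool holds
#' four 8-locus haplotypes whose five-locus core (block loci) has frequencies
#' 66.2/14.9/13.0/4.9 renormalised to sum to one; rs174545/rs174546 alleles
#' are deterministic copies of the rs174537 state (r^2 = 1 by construction)
#' and the three non-block loci (rs174575, rs174602, rs174589) are assigned
#' per pool haplotype by a fixed conditional table chosen so the marginal
#' minor-allele frequencies approximate the observed cohort frequencies
#' (0.25/0.17/0.18).
#'
#' Cluster membership follows a logistic model on the number of copies of the
#' major (GGGCC-core) haplotype; the defaults give phenotype cluster 1 a
#' major-allele homozygote enrichment of the observed magnitude and a
#' marginal cluster-1 share near one half. Group labels (MetS/CON) are drawn
#' conditional on cluster with P(MetS | cluster 1) = 109/180 and
#' P(MetS | cluster 2) = 57/174.
#'
#' Fatty acids are drawn log-normally per cluster, parameterised by median
#' (location) and interquartile range; rows are renormalised to the cluster
#' panel total. A multiplicative MetS shift on four FAs (16:1n-7, 18:0,
#' 18:2n-6, 20:3n-6) injects group-level contrast beyond cluster mixing.
#'
#' @param n_mets,n_con Group sizes (defaults 166 and 188; total 354).
#' @param n_genotyped Number of subjects with genotypes (default 330; the
#'   remainder get missing calls). `NULL` genotypes everyone.
#' @param seed Integer seed consumed once at the start of [generate_cohort()].
#' @return A list of class `generator_config`.
#' @export
#' @examples
#' cfg <- default_config(n_mets = 20, n_con = 20, n_genotyped = NULL)
#' sum(cfg$haplotype_pool$freq) # 1
default_config <- function(n_mets = 166L, n_con = 188L, n_genotyped = 330L,
                           seed = 1L) {
  # locus order (map order): rs174537 rs174545 rs174546 rs968567 rs174570
  #                          rs174575 rs174602 rs174589
  pool <- data.frame(
    hap  = c("GGGCCCTC", "TCATCGCC", "TCACTGTG", "TCACCCTG"),
    core = c("GGGCC", "TCATC", "TCACT", "TCACC"),
    freq = c(66.2, 14.9, 13.0, 4.9) / 99.0,
    stringsAsFactors = FALSE
  )
  fa <- fa_panel()
  # per-cluster location (median; mean for the three normally reported FAs)
  # and IQR (1.349 * SD where only SD is reported)
  loc1 <- c(0.268, 29.752, 0.105, 0.634, 14.59, 10.154, 1.556, 20.17,
            0.089, 0.198, 0.408, 3.363, 11.34, 1.091, 0.312, 0.199,
            0.909, 3.574)
  iqr1 <- c(0.110, 1.903, 0.041, 0.284, 1.349 * 1.34, 1.945, 0.467,
            1.349 * 2.07, 0.053, 0.081, 0.149, 0.708, 1.349 * 2.03,
            0.492, 0.103, 0.075, 0.192, 1.251)
  loc2 <- c(0.264, 29.091, 0.098, 0.484, 14.16, 8.930, 1.382, 25.31,
            0.074, 0.186, 0.381, 3.036, 10.34, 0.801, 0.284, 0.181,
            0.818, 3.018)
  iqr2 <- c(0.105, 2.072, 0.037, 0.183, 1.349 * 1.12, 1.453, 0.291,
            1.349 * 1.88, 0.036, 0.078, 0.121, 0.893, 1.349 * 1.95,
            0.284, 0.098, 0.072, 0.164, 0.973)
  fa_params <- data.frame(fa = fa, loc1 = loc1, iqr1 = iqr1,
                          loc2 = loc2, iqr2 = iqr2,
                          stringsAsFactors = FALSE)
  fa_group_mult <- setNames(rep(1, length(fa)), fa)
  fa_group_mult[c("16:1n-7", "18:0", "18:2n-6", "20:3n-6")] <-
    c(0.593 / 0.522, 14.43 / 13.84, 21.94 / 23.54, 3.351 / 3.011)

  clinical <- rbind(
    data.frame(group = "MetS", cluster = 1L,
               trait = c("weight", "waist", "glucose", "insulin", "tag"),
               location = c(90.0, 105, 5.7, 11.75, 2.86),
               scale = c(19.0, 1.349 * 11, 1.8, 7.17, 3.09),
               dist = c("lognormal", "normal", "lognormal", "lognormal",
                        "lognormal")),
    data.frame(group = "MetS", cluster = 2L,
               trait = c("weight", "waist", "glucose", "insulin", "tag"),
               location = c(85.8, 101, 5.3, 9.40, 2.43),
               scale = c(20.3, 1.349 * 9, 1.1, 5.83, 1.60),
               dist = c("lognormal", "normal", "lognormal", "lognormal",
                        "lognormal")),
    data.frame(group = "CON", cluster = 1L,
               trait = c("weight", "waist", "glucose", "insulin", "tag"),
               location = c(80.6, 95.5, 5.00, 8.59, 1.57),
               scale = c(23.8, 1.349 * 12.3, 0.60, 6.00, 1.10),
               dist = c("lognormal", "normal", "lognormal", "lognormal",
                        "lognormal")),
    data.frame(group = "CON", cluster = 2L,
               trait = c("weight", "waist", "glucose", "insulin", "tag"),
               location = c(73.7, 88.9, 4.90, 7.43, 1.27),
               scale = c(15.7, 1.349 * 10.6, 0.80, 5.30, 0.70),
               dist = c("lognormal", "normal", "lognormal", "lognormal",
                        "lognormal"))
  )

  cfg <- list(
    n_mets = as.integer(n_mets),
    n_con = as.integer(n_con),
    n_genotyped = if (is.null(n_genotyped)) NULL else as.integer(n_genotyped),
    seed = as.integer(seed),
    snps = fads_snp_panel(),
    haplotype_pool = pool,
    cluster_logit = list(
      intercept = -1.1,
      effects = setNames(c(0.8, 0, 0, 0), pool$hap)
    ),
    group_given_cluster = c(`1` = 109 / 180, `2` = 57 / 174),
    fa_params = fa_params,
    fa_group_mult = fa_group_mult,
    clinical_params = clinical,
    sex_prob_m = c(MetS = 98 / 166, CON = 101 / 188),
    age = list(MetS = c(mean = 55.2, sd = 10.6), CON = c(mean = 54.5, sd = 11.9))
  )
  class(cfg) <- "generator_config"
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks haplotype pool frequencies (non-negative, sum to 1 within 1e-9),
#' group sizes, haplotype string lengths and allele consistency with the SNP
#' panel, and positivity of FA scale parameters.
#'
#' @param config A `generator_config`.
#' @return `config`, invisibly, or an error.
#' @export
validate_config <- function(config) {
  pool <- config$haplotype_pool
  if (nrow(pool) < 1L) stop("haplotype pool is empty")
  if (any(pool$freq < 0)) stop("haplotype frequencies must be >= 0")
  if (abs(sum(pool$freq) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1 (got ", sum(pool$freq), ")")
  if (config$n_mets < 0L || config$n_con < 0L || config$n_mets + config$n_con < 1L)
    stop("need at least one subject")
  L <- nrow(config$snps)
  if (any(nchar(pool$hap) != L))
    stop("every haplotype string must have length ", L)
  am <- do.call(rbind, strsplit(pool$hap, ""))
  for (j in seq_len(L)) {
    ok <- am[, j] %in% c(config$snps$major[j], config$snps$minor[j])
    if (!all(ok))
      stop("haplotype allele at locus ", config$snps$snp[j],
           " outside its allele set")
  }
  if (any(config$fa_params$iqr1 <= 0) || any(config$fa_params$iqr2 <= 0))
    stop("non-positive FA scale parameter")
  if (!all(names(config$cluster_logit$effects) == pool$hap))
    stop("cluster_logit effects must be named by pool haplotypes")
  invisible(config)
}

# sdlog of a log-normal with median m and interquartile range w:
# q75 * q25 = m^2 and q75 - q25 = w give q75 in closed form.
lnorm_sdlog <- function(median, iqr) {
  q75 <- (iqr + sqrt(iqr^2 + 4 * median^2)) / 2
  log(q75 / median) / qnorm(0.75)
}

#' Draw haplotype pairs under random mating
#'
#' Each subject receives two independent draws from the pool, so genotypes
#' are in Hardy-Weinberg equilibrium in expectation.
#'
#' @param config A `generator_config`.
#' @param n Number of subjects.
#' @return Integer matrix `n x 2` of row indices into `config$haplotype_pool`.
#' @export
draw_haplotype_pairs <- function(config, n) {
  pool <- config$haplotype_pool
  if (nrow(pool) == 0L) stop("haplotype pool is empty")
  matrix(sample.int(nrow(pool), size = 2L * n, replace = TRUE,
                    prob = pool$freq), ncol = 2L)
}

#' Collapse haplotype pairs to unphased genotypes
#'
#' Phase is discarded: each call is the unordered allele pair, written with
#' alleles in alphabetical order.
#'
#' @param pairs Matrix from [draw_haplotype_pairs()].
#' @param config A `generator_config` (supplies the pool and SNP panel).
#' @return A `genotype_matrix`.
#' @export
collapse_to_genotypes <- function(pairs, config) {
  pool <- config$haplotype_pool
  snps <- config$snps
  a1 <- do.call(rbind, strsplit(pool$hap[pairs[, 1]], ""))
  a2 <- do.call(rbind, strsplit(pool$hap[pairs[, 2]], ""))
  calls <- matrix(paste(pmin(a1, a2), pmax(a1, a2), sep = "/"),
                  nrow = nrow(pairs), ncol = nrow(snps))
  colnames(calls) <- snps$snp
  genotype_matrix(calls, snps)
}

#' Construct a genotype matrix
#'
#' @param calls Character matrix, subjects x SNPs, entries `"X/Y"` with
#'   alleles in alphabetical order, or `NA` for missing.
#' @param snps SNP metadata data.frame (see [fads_snp_panel()]).
#' @param ids Optional subject ids (default `S1..Sn`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snps, ids = NULL) {
  stopifnot(is.matrix(calls), ncol(calls) == nrow(snps))
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(calls)))
  rownames(calls) <- ids
  colnames(calls) <- snps$snp
  structure(list(calls = calls, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "subjects x", ncol(x$calls),
      "SNPs;", sum(is.na(x$calls)), "missing calls\n")
  invisible(x)
}

#' Minor-allele dosage per subject per SNP
#'
#' @param genotypes A `genotype_matrix`.
#' @return Integer matrix of minor-allele counts (0/1/2), `NA` where missing.
#' @export
geno_dosage <- function(genotypes) {
  calls <- genotypes$calls
  snps <- genotypes$snps
  out <- matrix(NA_integer_, nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  for (j in seq_len(ncol(calls))) {
    al <- strsplit(calls[, j], "/", fixed = TRUE)
    out[, j] <- vapply(al, function(a) {
      if (length(a) != 2L || anyNA(a)) return(NA_integer_)
      sum(a == snps$minor[j])
    }, integer(1))
  }
  out
}

#' Assign latent phenotype cluster labels
#'
#' P(cluster 1) = logistic(intercept + effect(h1) + effect(h2)).
#'
#' @param pairs Haplotype pair index matrix.
#' @param config A `generator_config`.
#' @return Integer labels in `{1, 2}`.
#' @export
assign_cluster_labels <- function(pairs, config) {
  eff <- config$cluster_logit$effects
  eta <- config$cluster_logit$intercept +
    eff[pairs[, 1]] + eff[pairs[, 2]]
  ifelse(runif(nrow(pairs)) < plogis(unname(eta)), 1L, 2L)
}

#' Generate fatty acid profiles conditional on cluster
#'
#' Values are drawn log-normally per FA with cluster-specific median and IQR,
#' optionally shifted multiplicatively for MetS subjects, then each row is
#' renormalised to its cluster's panel total (the sum of the cluster's
#' location parameters), preserving percent-of-total scale.
#'
#' @param labels Cluster labels in `{1, 2}`.
#' @param config A `generator_config`.
#' @param group Optional group factor/character (`"MetS"`/`"CON"`); when
#'   given, `config$fa_group_mult` is applied to MetS rows before
#'   renormalisation.
#' @param noise If `FALSE`, returns the (renormalised) location vectors
#'   without sampling (degenerate, zero-variance draw).
#' @return Numeric matrix, subjects x 18 FAs, columns named by [fa_panel()].
#' @export
generate_fa_profiles <- function(labels, config, group = NULL, noise = TRUE) {
  fp <- config$fa_params
  if (!setequal(fp$fa, fa_panel()))
    stop("fa_params must cover the 18-FA panel")
  if (any(fp$iqr1 <= 0) || any(fp$iqr2 <= 0))
    stop("non-positive FA scale parameter")
  n <- length(labels)
  K <- nrow(fp)
  loc <- cbind(fp$loc1, fp$loc2)
  sdl <- cbind(lnorm_sdlog(fp$loc1, fp$iqr1), lnorm_sdlog(fp$loc2, fp$iqr2))
  X <- matrix(0, n, K, dimnames = list(NULL, fp$fa))
  for (k in seq_len(K)) {
    m <- loc[k, labels]
    s <- sdl[k, labels]
    X[, k] <- if (noise) rlnorm(n, meanlog = log(m), sdlog = s) else m
  }
  if (!is.null(group)) {
    mult <- config$fa_group_mult[fp$fa]
    is_mets <- as.character(group) == "MetS"
    if (any(is_mets))
      X[is_mets, ] <- sweep(X[is_mets, , drop = FALSE], 2, mult, `*`)
  }
  totals <- c(sum(fp$loc1), sum(fp$loc2))[labels]
  X * (totals / rowSums(X))
}

#' Generate a complete synthetic cohort
#'
#' End-to-end generation: haplotype pairs (random mating), latent cluster
#' labels, MetS/CON group labels conditional on cluster, fatty acid profiles,
#' clinical covariates (weight, waist, glucose, insulin, triacylglycerols,
#' sex, age) and the unphased genotype matrix restricted to the genotyped
#' subset. Consumes the RNG stream once, seeded from `config$seed`, so two
#' calls with the same config are identical.
#'
#' @param config A `generator_config` from [default_config()].
#' @return A list with elements `cohort` (data.frame: id, group, sex, age,
#'   clinical traits, homa_ir, 18 FA columns), `genotypes`
#'   (`genotype_matrix`, missing calls for non-genotyped subjects) and
#'   `truth` (per-subject true haplotype strings and cluster, plus config).
#' @export
#' @examples
#' sim <- generate_cohort(default_config(n_mets = 30, n_con = 30,
#'                                       n_genotyped = NULL, seed = 7))
#' table(sim$cohort$group, sim$truth$cluster)
generate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_mets + config$n_con
  pairs <- draw_haplotype_pairs(config, n)
  cluster <- assign_cluster_labels(pairs, config)

  p_mets <- config$group_given_cluster[as.character(cluster)]
  if (config$n_mets == 0L) p_mets[] <- 0
  if (config$n_con == 0L) p_mets[] <- 1
  group <- ifelse(runif(n) < p_mets, "MetS", "CON")

  fa <- generate_fa_profiles(cluster, config, group = group)

  cp <- config$clinical_params
  traits <- unique(cp$trait)
  clin <- matrix(NA_real_, n, length(traits), dimnames = list(NULL, traits))
  for (g in c("MetS", "CON")) for (cl in 1:2) {
    idx <- which(group == g & cluster == cl)
    if (!length(idx)) next
    sub <- cp[cp$group == g & cp$cluster == cl, ]
    for (r in seq_len(nrow(sub))) {
      if (sub$dist[r] == "normal") {
        clin[idx, sub$trait[r]] <- rnorm(length(idx), sub$location[r],
                                         sub$scale[r] / 1.349)
      } else {
        clin[idx, sub$trait[r]] <- rlnorm(
          length(idx), meanlog = log(sub$location[r]),
          sdlog = lnorm_sdlog(sub$location[r], sub$scale[r]))
      }
    }
  }

  sex <- ifelse(runif(n) < config$sex_prob_m[group], "M", "F")
  age <- round(rnorm(n, mean = sapply(config$age[group], `[[`, "mean"),
                     sd = sapply(config$age[group], `[[`, "sd")), 1)

  ids <- sprintf("S%03d", seq_len(n))
  cohort <- data.frame(id = ids, group = group, sex = sex, age = age,
                       stringsAsFactors = FALSE, check.names = FALSE)
  cohort <- cbind(cohort, as.data.frame(clin, check.names = FALSE))
  cohort$homa_ir <- homa_ir(cohort$insulin, cohort$glucose)
  cohort <- cbind(cohort, as.data.frame(fa, check.names = FALSE))

  geno <- collapse_to_genotypes(pairs, config)
  rownames(geno$calls) <- ids
  n_geno <- config$n_genotyped %||% n
  if (n_geno > n) stop("n_genotyped exceeds cohort size")
  if (n_geno < n) {
    drop <- sample.int(n, n - n_geno)
    geno$calls[drop, ] <- NA_character_
  }

  truth <- list(
    hap1 = config$haplotype_pool$hap[pairs[, 1]],
    hap2 = config$haplotype_pool$hap[pairs[, 2]],
    cluster = cluster,
    config = config
  )
  list(cohort = cohort, genotypes = geno, truth = truth)
}
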