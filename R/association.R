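# Per-SNP allele/genotype contingency tables, Pearson chi-squared tests with
# optional Yates continuity correction, Hardy-Weinberg testing and the
# case-control association scan with Benjamini-Hochberg adjustment.
# Convention mirrored throughout: genotype (2x3) tests are uncorrected,
# allele (2x2) tests use the Yates correction.

#' Pearson chi-squared test of a contingency table
#'
#' chi2 = sum (O - E)^2 / E with E from the product of margins; with
#' `correction = "yates"` (2x2 only) each |O - E| is reduced by 0.5, floored
#' at 0. df = (r-1)(c-1); p from the chi-squared distribution.
#'
#' @param table Numeric matrix (or `table`) of observed counts.
#' @param correction `"none"` or `"yates"`.
#' @return An object of class `contingency_result`: list with `observed`,
#'   `expected`, `chi2`, `df`, `p_raw`, `correction` (and `p_adjusted` once
#'   set by a batch caller).
#' @export
#' @examples
#' pearson_chi2(rbind(c(109, 57), c(71, 117)), "yates")$chi2 # 26.346
pearson_chi2 <- function(table, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  O <- matrix(as.numeric(table), nrow(table), ncol(table),
              dimnames = dimnames(table))
  if (any(O < 0) || sum(O) <= 0) stop("counts must be >= 0 with positive total")
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0)) stop("zero row margin: row ", which(rs == 0)[1])
  if (any(cs == 0)) stop("zero column margin: column ", which(cs == 0)[1])
  if (correction == "yates" && !all(dim(O) == 2L))
    stop("Yates correction applies to 2x2 tables only")
  E <- outer(rs, cs) / sum(O)
  dev <- abs(O - E)
  if (correction == "yates") dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  structure(list(observed = O, expected = E, chi2 = chi2, df = df,
                 p_raw = pchisq(chi2, df, lower.tail = FALSE),
                 p_adjusted = NA_real_, correction = correction),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("chi2 = %.4f, df = %d, p = %.4g (correction: %s)\n",
              x$chi2, x$df, x$p_raw, x$correction))
  invisible(x)
}

#' Genotype count table for one SNP across two strata
#'
#' Counts ordered (AA, Aa, aa) by the SNP's declared major allele A. Missing
#' genotypes are dropped; the number dropped is attached as attribute
#' `n_missing`. Zero-count genotype columns are retained.
#'
#' @param genotypes A `genotype_matrix`.
#' @param snp SNP id.
#' @param grouping Two-level factor/character, one entry per subject.
#' @return 2x3 integer matrix (strata x genotype classes).
#' @export
genotype_table <- function(genotypes, snp, grouping) {
  j <- match(snp, genotypes$snps$snp)
  if (is.na(j)) stop("unknown SNP: ", snp)
  A <- genotypes$snps$major[j]; a <- genotypes$snps$minor[j]
  calls <- genotypes$calls[, j]
  g <- factor(grouping)
  if (nlevels(g) != 2L) stop("grouping must have two levels")
  keep <- !is.na(calls) & !is.na(g)
  calls <- calls[keep]; g <- droplevels(g[keep])
  if (nlevels(g) != 2L) stop("empty stratum for SNP ", snp)
  classes <- c(paste(sort(c(A, A)), collapse = "/"),
               paste(sort(c(A, a)), collapse = "/"),
               paste(sort(c(a, a)), collapse = "/"))
  if (!all(calls %in% classes))
    stop("allele mismatch at ", snp, ": unexpected call ",
         setdiff(calls, classes)[1])
  tab <- table(g, factor(calls, levels = classes))
  out <- matrix(as.integer(tab), 2L, 3L,
                dimnames = list(levels(g), c("AA", "Aa", "aa")))
  attr(out, "n_missing") <- sum(!keep)
  attr(out, "alleles") <- c(A = A, a = a)
  out
}

#' Allele count table from a genotype table
#'
#' Per stratum: A = 2 AA + Aa, a = Aa + 2 aa, so each allele row total is
#' twice the genotype row total.
#'
#' @param genotype_table 2x3 matrix of (AA, Aa, aa) counts.
#' @return 2x2 matrix of (A, a) counts.
#' @export
#' @examples
#' allele_table(rbind(c(52, 38, 4), c(18, 26, 12))) # 142 46 / 62 50
allele_table <- function(genotype_table) {
  stopifnot(ncol(genotype_table) == 3L)
  out <- cbind(A = 2L * genotype_table[, 1] + genotype_table[, 2],
               a = genotype_table[, 2] + 2L * genotype_table[, 3])
  rownames(out) <- rownames(genotype_table)
  out
}

#' Hardy-Weinberg equilibrium test
#'
#' Expected counts n (p^2, 2pq, q^2) with p estimated from the data; Pearson
#' chi-squared with df = 1 (biallelic locus, one estimated allele frequency).
#' A monomorphic SNP returns p = 1 with a warning.
#'
#' @param genotype_counts Numeric vector of length 3: (AA, Aa, aa).
#' @return A `contingency_result` (observed/expected are length-3 vectors).
#' @export
#' @examples
#' hwe_test(c(70, 64, 16))$p_raw # 0.81
hwe_test <- function(genotype_counts) {
  stopifnot(length(genotype_counts) == 3L)
  O <- as.numeric(genotype_counts)
  n <- sum(O)
  if (n < 1) stop("need n >= 1")
  p <- (2 * O[1] + O[2]) / (2 * n)
  if (p == 0 || p == 1) {
    warning("monomorphic SNP; HWE test undefined, returning p = 1")
    E <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    return(structure(list(observed = O, expected = E, chi2 = 0, df = 1L,
                          p_raw = 1, p_adjusted = NA_real_,
                          correction = "none"),
                     class = "contingency_result"))
  }
  E <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((O - E)^2 / E)
  structure(list(observed = O, expected = E, chi2 = chi2, df = 1L,
                 p_raw = pchisq(chi2, 1, lower.tail = FALSE),
                 p_adjusted = NA_real_, correction = "none"),
            class = "contingency_result")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` with input validation.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values (monotone in rank, capped at 1).
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values)) stop("NaN/NA p-value in input")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Case-control association scan over SNPs
#'
#' For each SNP: genotype test (2x3, uncorrected), allele test (2x2, Yates)
#' and a Hardy-Weinberg test per stratum. BH adjustment is applied across the
#' scan's genotype p-values and, separately, across its allele p-values.
#'
#' @param genotypes A `genotype_matrix`.
#' @param grouping Two-level grouping, one entry per subject.
#' @param snps SNP ids to scan (default: all in the matrix).
#' @param on_error `"stop"` propagates per-SNP errors (e.g. a zero genotype
#'   margin); `"na"` records NA statistics for the offending SNP with a
#'   warning and continues.
#' @return data.frame with one row per SNP: counts summary, `chi2_genotype`,
#'   `p_genotype`, `p_genotype_bh`, `chi2_allele`, `p_allele`, `p_allele_bh`,
#'   `hwe_p_stratum1`, `hwe_p_stratum2`, `n_missing`.
#' @export
association_scan <- function(genotypes, grouping, snps = genotypes$snps$snp,
                             on_error = c("stop", "na")) {
  on_error <- match.arg(on_error)
  if (length(snps) < 1L) stop("need >= 1 SNP")
  one <- function(s) {
    gt <- genotype_table(genotypes, s, grouping)
    at <- allele_table(gt)
    gres <- pearson_chi2(gt, "none")
    ares <- pearson_chi2(at, "yates")
    suppressWarnings(data.frame(
      snp = s,
      chi2_genotype = gres$chi2, p_genotype = gres$p_raw,
      chi2_allele = ares$chi2, p_allele = ares$p_raw,
      hwe_p_stratum1 = hwe_test(gt[1, ])$p_raw,
      hwe_p_stratum2 = hwe_test(gt[2, ])$p_raw,
      n_missing = attr(gt, "n_missing"),
      stringsAsFactors = FALSE))
  }
  rows <- lapply(snps, function(s) {
    if (on_error == "stop") return(one(s))
    tryCatch(one(s), error = function(e) {
      warning("SNP ", s, " skipped: ", conditionMessage(e))
      data.frame(snp = s, chi2_genotype = NA_real_, p_genotype = NA_real_,
                 chi2_allele = NA_real_, p_allele = NA_real_,
                 hwe_p_stratum1 = NA_real_, hwe_p_stratum2 = NA_real_,
                 n_missing = NA_integer_, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_genotype)
  out$p_genotype_bh <- NA_real_
  out$p_allele_bh <- NA_real_
  out$p_genotype_bh[ok] <- bh_adjust(out$p_genotype[ok])
  out$p_allele_bh[ok] <- bh_adjust(out$p_allele[ok])
  out
}
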