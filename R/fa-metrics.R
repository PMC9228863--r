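# Fatty acid panel summaries: family sums, desaturase activity indices,
# HOMA-IR and classical two-group comparisons with Benjamini-Hochberg
# adjustment.

#' Fatty acid family membership for the panel sums
#'
#' The n-position suffix determines the family; the four lists partition the
#' 18-FA panel.
#'
#' @return Named list with members `sfa`, `mfa`, `n6`, `n3`.
#' @export
fa_sum_members <- function() {
  list(
    sfa = c("14:0", "16:0", "18:0"),
    mfa = c("16:1n-9", "16:1n-7", "18:1n-9", "18:1n-7"),
    n6  = c("18:2n-6", "18:3n-6", "20:2n-6", "20:3n-6", "20:4n-6",
            "22:4n-6", "22:5n-6"),
    n3  = c("18:3n-3", "20:5n-3", "22:5n-3", "22:6n-3")
  )
}

as_fa_matrix <- function(profile) {
  if (is.data.frame(profile)) profile <- as.matrix(profile[, fa_panel(), drop = FALSE])
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1,
                                               dimnames = list(NULL, names(profile)))
  missing <- setdiff(fa_panel(), colnames(profile))
  if (length(missing)) stop("missing FA key(s): ", paste(missing, collapse = ", "))
  if (any(profile[, fa_panel()] < 0, na.rm = TRUE)) stop("FA values must be >= 0")
  profile[, fa_panel(), drop = FALSE]
}

#' Fatty acid family sums
#'
#' Sums of saturated, monounsaturated, n-6 and n-3 fatty acids over the fixed
#' membership lists of [fa_sum_members()], in percent of total FA.
#'
#' @param profile Named numeric vector, matrix or data.frame holding the 18
#'   panel FAs (percent of total).
#' @return data.frame with columns `sum_sfa`, `sum_mfa`, `sum_n6`, `sum_n3`,
#'   one row per input row.
#' @export
#' @examples
#' p <- setNames(rep(0, 18), fa_panel()); p["16:0"] <- 30
#' fa_sums(p)$sum_sfa # 30
fa_sums <- function(profile) {
  x <- as_fa_matrix(profile)
  m <- fa_sum_members()
  data.frame(
    sum_sfa = rowSums(x[, m$sfa, drop = FALSE]),
    sum_mfa = rowSums(x[, m$mfa, drop = FALSE]),
    sum_n6  = rowSums(x[, m$n6, drop = FALSE]),
    sum_n3  = rowSums(x[, m$n3, drop = FALSE])
  )
}

#' Desaturase activity indices (product/precursor ratios)
#'
#' D9D-16 = 16:1n-7 / 16:0, D9D-18 = 18:1n-9 / 18:0,
#' D6D (n-6) = 18:3n-6 / 18:2n-6, D5D (n-6) = 20:4n-6 / 20:3n-6.
#' A zero denominator yields `NaN` (flagged undefined, no error); ratios are
#' computed per subject, never as ratios of group summaries.
#'
#' @inheritParams fa_sums
#' @return data.frame with columns `d9d16`, `d9d18`, `d6d_n6`, `d5d_n6`.
#' @export
#' @examples
#' p <- setNames(rep(1, 18), fa_panel())
#' p[c("20:4n-6", "20:3n-6")] <- c(4, 2)
#' desaturase_indices(p)$d5d_n6 # 2
desaturase_indices <- function(profile) {
  x <- as_fa_matrix(profile)
  ratio <- function(num, den) {
    r <- x[, num] / x[, den]
    r[x[, den] == 0] <- NaN
    r
  }
  data.frame(
    d9d16  = ratio("16:1n-7", "16:0"),
    d9d18  = ratio("18:1n-9", "18:0"),
    d6d_n6 = ratio("18:3n-6", "18:2n-6"),
    d5d_n6 = ratio("20:4n-6", "20:3n-6")
  )
}

#' HOMA-IR insulin resistance index
#'
#' fasting insulin (uU/mL) x fasting glucose (mmol/L) / 22.5. Vectorised.
#'
#' @param insulin_mU_per_L Fasting insulin, mU/L (= uU/mL).
#' @param glucose_mmol_per_L Fasting glucose, mmol/L.
#' @return Numeric ratio.
#' @export
#' @examples
#' homa_ir(10.7, 5.6) # 2.6631...
homa_ir <- function(insulin_mU_per_L, glucose_mmol_per_L) {
  if (any(insulin_mU_per_L < 0, na.rm = TRUE) ||
      any(glucose_mmol_per_L < 0, na.rm = TRUE))
    stop("insulin and glucose must be >= 0")
  insulin_mU_per_L * glucose_mmol_per_L / 22.5
}

#' Two-group comparison of a continuous trait
#'
#' Uses the independent t-test when both groups pass Shapiro-Wilk normality
#' at 0.05, otherwise the Wilcoxon rank-sum test. Constant traits fall back
#' to the rank-sum test with a warning.
#'
#' @param table data.frame holding the trait and the grouping column.
#' @param trait Column name of the trait.
#' @param group_a,group_b The two grouping levels to compare.
#' @param group_col Name of the grouping column (default `"group"`).
#' @return List with `trait`, `test` ("t" or "wilcoxon"), `statistic`,
#'   `p_value`, group summaries (`median_a`, `median_b`, `n_a`, `n_b`).
#' @export
compare_groups <- function(table, trait, group_a, group_b,
                           group_col = "group") {
  xa <- table[[trait]][table[[group_col]] == group_a]
  xb <- table[[trait]][table[[group_col]] == group_b]
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (length(xa) < 3L || length(xb) < 3L)
    stop("need >= 3 observations per group for trait ", trait)
  constant <- (var(xa) == 0 || var(xb) == 0)
  if (constant) {
    warning("trait ", trait, " constant within a group; using rank-sum test")
    normal <- FALSE
  } else {
    sw <- function(x) shapiro.test(if (length(x) > 5000) sample(x, 5000) else x)$p.value
    normal <- sw(xa) > 0.05 && sw(xb) > 0.05
  }
  if (normal) {
    ht <- t.test(xa, xb)
    test <- "t"
  } else {
    ht <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE))
    test <- "wilcoxon"
  }
  list(trait = trait, test = test, statistic = unname(ht$statistic),
       p_value = ht$p.value, median_a = median(xa), median_b = median(xb),
       n_a = length(xa), n_b = length(xb))
}

#' Batch two-group comparisons with BH adjustment
#'
#' Runs [compare_groups()] over several traits and adjusts the raw p-values
#' with the Benjamini-Hochberg step-up procedure (one family per call).
#'
#' @inheritParams compare_groups
#' @param traits Character vector of trait columns.
#' @return data.frame: trait, test, statistic, medians, p_raw, p_adjusted.
#' @export
compare_traits <- function(table, traits, group_a, group_b,
                           group_col = "group") {
  rows <- lapply(traits, function(tr)
    compare_groups(table, tr, group_a, group_b, group_col))
  out <- data.frame(
    trait = vapply(rows, `[[`, "", "trait"),
    test = vapply(rows, `[[`, "", "test"),
    statistic = vapply(rows, `[[`, 0, "statistic"),
    median_a = vapply(rows, `[[`, 0, "median_a"),
    median_b = vapply(rows, `[[`, 0, "median_b"),
    p_raw = vapply(rows, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE
  )
  out$p_adjusted <- bh_adjust(out$p_raw)
  out
}

#' Covariate-adjusted group effect (ANCOVA)
#'
#' Linear model `trait ~ group + covariate`; reports the group effect and its
#' p-value (e.g. a body-weight-adjusted cluster contrast).
#'
#' @param data data.frame.
#' @param trait,group,covariate Column names.
#' @return List with `estimate` (group coefficient), `p_value`, `n`, `model`.
#' @export
ancova_group_effect <- function(data, trait, group, covariate) {
  d <- data[, c(trait, group, covariate)]
  d <- d[complete.cases(d), ]
  if (nrow(d) <= 3L) stop("need n > 3 complete observations")
  if (var(d[[covariate]]) == 0) stop("covariate is constant")
  g <- factor(d[[group]])
  if (nlevels(g) != 2L) stop("group must have exactly two levels")
  if (var(tapply(d[[covariate]], g, mean)) > 0 &&
      isTRUE(all.equal(var(d[[covariate]] -
        ave(d[[covariate]], g)), 0)))
    stop("group and covariate are collinear")
  fit <- lm(d[[trait]] ~ g + d[[covariate]])
  sm <- summary(fit)$coefficients
  list(estimate = unname(coef(fit)[2]), p_value = sm[2, 4],
       n = nrow(d), model = fit)
}
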