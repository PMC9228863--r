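# Stepwise forward variable selection for two-group linear discriminant
# analysis on the Wilks' lambda criterion, plus the fitted discriminant and
# its resubstitution accuracy.

sscp <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  crossprod(Xc)
}

#' Wilks' lambda for a variable subset
#'
#' Lambda = det(W) / det(T), where W is the pooled within-group and T the
#' total cross-product (SSCP) matrix over the chosen variables. Smaller
#' values mean better group separation; the empty subset gives 1 by
#' convention.
#'
#' @param X Numeric matrix or data.frame of candidate variables.
#' @param labels Group labels (any type coercible to factor; >= 2 groups).
#' @param variable_subset Character vector of column names (default: all).
#' @return Lambda in (0, 1].
#' @export
#' @examples
#' X <- cbind(v = c(0, 1, 2, 3))
#' wilks_lambda(X, c("a", "a", "b", "b"), "v") # 0.2
wilks_lambda <- function(X, labels, variable_subset = colnames(X)) {
  if (length(variable_subset) == 0L) return(1)
  X <- as.matrix(as.data.frame(X, check.names = FALSE)[, variable_subset,
                                                       drop = FALSE])
  storage.mode(X) <- "double"
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  if (nrow(X) <= length(variable_subset) + nlevels(g))
    stop("need n > |subset| + number of groups")
  Tm <- sscp(X)
  Wm <- Reduce(`+`, lapply(levels(g), function(l) sscp(X[g == l, , drop = FALSE])))
  dT <- det(Tm)
  if (!is.finite(dT) || dT <= .Machine$double.eps * max(diag(Tm))^ncol(Tm))
    stop("singular total scatter on subset: ",
         paste(variable_subset, collapse = ", "))
  det(Wm) / dT
}

#' F-to-enter statistic for stepwise selection
#'
#' The classical partial-Wilks F for adding one variable when `p_in`
#' variables are already entered:
#' F = ((n - g - p_in) / (g - 1)) * (lambda_before / lambda_after - 1),
#' with (g - 1, n - g - p_in) degrees of freedom. For the first variable
#' with two groups this equals the one-way ANOVA F.
#'
#' @param lambda_before,lambda_after Wilks' lambda before/after entry.
#' @param n Number of observations.
#' @param g Number of groups.
#' @param p_in Number of variables already entered.
#' @return The F statistic.
#' @export
f_to_enter <- function(lambda_before, lambda_after, n, g, p_in) {
  if (!(lambda_after > 0 && lambda_after <= lambda_before && lambda_before <= 1))
    stop("need 0 < lambda_after <= lambda_before <= 1")
  df2 <- n - g - p_in
  if (df2 <= 0) stop("nonpositive degrees of freedom")
  (df2 / (g - 1)) * (lambda_before / lambda_after - 1)
}

#' Stepwise forward variable selection on Wilks' lambda
#'
#' Greedily enters the candidate with the largest F-to-enter while it meets
#' the entry threshold and fewer than `max_vars` variables are in. Ties are
#' broken by lexicographic variable name; candidates whose entry makes the
#' total scatter singular are skipped with a warning.
#'
#' @param X Numeric matrix or data.frame of candidates.
#' @param labels Group labels.
#' @param f_enter Entry threshold for F (default 4.0).
#' @param max_vars Maximum number of variables to enter (default 6).
#' @return An object of class `selection_trace`: data.frame with columns
#'   `step`, `variable`, `lambda`, `F`; attributes `selected` (character) and
#'   `stopping_reason`.
#' @export
stepwise_select <- function(X, labels, f_enter = 4.0, max_vars = 6L) {
  X <- as.data.frame(X, check.names = FALSE)
  cand <- sort(colnames(X))
  if (length(cand) < 2L) stop("need >= 2 candidate variables")
  g <- nlevels(factor(labels))
  n <- nrow(X)
  entered <- character(0)
  lam <- 1
  rows <- list()
  reason <- "maximum number of variables entered"
  while (length(entered) < max_vars) {
    best <- NULL
    for (v in setdiff(cand, entered)) {   # cand sorted: lexicographic ties
      lam_v <- tryCatch(wilks_lambda(X, labels, c(entered, v)),
                        error = function(e) {
                          warning("skipping ", v, ": ", conditionMessage(e))
                          NA_real_
                        })
      if (is.na(lam_v)) next
      lam_v <- min(lam_v, lam)  # guard against tiny numerical overshoot
      Fv <- f_to_enter(lam, lam_v, n, g, length(entered))
      if (is.null(best) || Fv > best$F) best <- list(v = v, lambda = lam_v, F = Fv)
    }
    if (is.null(best) || best$F < f_enter) {
      reason <- "no candidate reached F threshold"
      break
    }
    entered <- c(entered, best$v)
    lam <- best$lambda
    rows[[length(rows) + 1L]] <- data.frame(
      step = length(entered), variable = best$v,
      lambda = best$lambda, F = best$F, stringsAsFactors = FALSE)
  }
  trace <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = integer(0), variable = character(0),
               lambda = numeric(0), F = numeric(0))
  structure(trace, selected = entered, stopping_reason = reason,
            class = c("selection_trace", "data.frame"))
}

#' Fit a two-group linear discriminant
#'
#' Direction proportional to W^-1 (m1 - m2) (generalised inverse, so exactly
#' collinear variables are tolerated), scaled to unit norm under the pooled
#' within-group covariance; midpoint threshold with equal priors;
#' resubstitution accuracy reported.
#'
#' @param X Numeric matrix or data.frame.
#' @param labels Group labels (exactly two levels).
#' @param variable_subset Columns to use (default: all).
#' @return An object of class `lda_model`: list with `direction`,
#'   `centroids`, `threshold`, `accuracy`, `levels`, `variables`.
#' @export
fit_lda <- function(X, labels, variable_subset = colnames(X)) {
  X <- as.matrix(as.data.frame(X, check.names = FALSE)[, variable_subset,
                                                       drop = FALSE])
  storage.mode(X) <- "double"
  g <- factor(labels)
  if (nlevels(g) != 2L) stop("need exactly two groups")
  l1 <- levels(g)[1]; l2 <- levels(g)[2]
  X1 <- X[g == l1, , drop = FALSE]; X2 <- X[g == l2, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  W <- sscp(X1) + sscp(X2)
  Sw <- W / (nrow(X) - 2L)
  d <- drop(MASS::ginv(Sw) %*% (m1 - m2))
  nrm <- sqrt(drop(t(d) %*% Sw %*% d))
  if (nrm > 0) d <- d / nrm
  s1 <- drop(m1 %*% d); s2 <- drop(m2 %*% d)
  thr <- (s1 + s2) / 2
  scores <- drop(X %*% d)
  pred <- ifelse((scores - thr) * sign(s1 - s2) >= 0, l1, l2)
  structure(list(direction = setNames(d, colnames(X)),
                 centroids = rbind(m1, m2), threshold = thr,
                 accuracy = mean(pred == as.character(g)),
                 levels = c(l1, l2), variables = colnames(X)),
            class = "lda_model")
}

#' Classify with a fitted discriminant
#'
#' @param object An `lda_model`.
#' @param newdata Matrix/data.frame holding the model's variables.
#' @param ... Unused.
#' @return Character vector of predicted group labels.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata,
                               check.names = FALSE)[, object$variables,
                                                    drop = FALSE])
  scores <- drop(X %*% object$direction)
  s1 <- drop(object$centroids[1, ] %*% object$direction)
  s2 <- drop(object$centroids[2, ] %*% object$direction)
  ifelse((scores - object$threshold) * sign(s1 - s2) >= 0,
         object$levels[1], object$levels[2])
}
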