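# Agglomerative hierarchical clustering with Ward's minimum-variance
# criterion, implemented via the Lance-Williams recurrence on squared
# Euclidean dissimilarities. Merge heights are reported as the increase in
# total within-cluster sum of squares (delta-SS), which makes the
# conservation law "sum of heights = total SS about the grand mean" exact.

#' Ward minimum-variance linkage
#'
#' Greedy agglomeration minimising the increase in total within-cluster sum
#' of squares. Dissimilarities are initialised to half the squared Euclidean
#' distance (the delta-SS of merging two singletons) and updated with the
#' Lance-Williams recurrence
#' d(ij,k) = ((ni+nk) d(i,k) + (nj+nk) d(j,k) - nk d(i,j)) / (ni+nj+nk).
#' Ties are broken by the smallest (min leaf id of A, min leaf id of B).
#'
#' @param X Numeric matrix or data.frame (subjects x variables), no missing
#'   values.
#' @return An object of class `ward_dendrogram`: list with `merge` (n-1 x 2,
#'   hclust convention: negative = leaf index, positive = earlier merge),
#'   `height` (delta-SS per merge), `n`, `labels`.
#' @export
#' @examples
#' d <- ward_linkage(cbind(c(0, 1, 10, 11)))
#' d$height # 0.5 0.5 50
ward_linkage <- function(X) {
  X <- as.matrix(as.data.frame(X, check.names = FALSE))
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) stop("NaN/NA in input")
  n <- nrow(X)
  if (n < 2L) stop("need n >= 2 observations")
  labels <- rownames(X) %||% as.character(seq_len(n))

  D <- as.matrix(dist(X))^2 / 2     # delta-SS for singleton merges
  diag(D) <- Inf
  size <- rep(1L, n)
  min_leaf <- seq_len(n)            # for deterministic tie-breaking
  node <- -seq_len(n)               # hclust merge coding of each active cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    idx <- which(active)
    Dsub <- D[idx, idx, drop = FALSE]
    dmin <- min(Dsub)
    hit <- which(Dsub == dmin, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    a <- idx[hit[, 1]]; b <- idx[hit[, 2]]
    lo <- pmin(min_leaf[a], min_leaf[b]); hi <- pmax(min_leaf[a], min_leaf[b])
    pick <- order(lo, hi)[1]
    i <- a[pick]; j <- b[pick]
    if (min_leaf[j] < min_leaf[i]) { tmp <- i; i <- j; j <- tmp }

    height[s] <- D[i, j]
    merge[s, ] <- sort(c(node[i], node[j]))

    ni <- size[i]; nj <- size[j]
    k <- idx[idx != i & idx != j]
    if (length(k)) {
      D[i, k] <- D[k, i] <-
        ((ni + size[k]) * D[i, k] + (nj + size[k]) * D[j, k] -
           size[k] * D[i, j]) / (ni + nj + size[k])
    }
    size[i] <- ni + nj
    min_leaf[i] <- min(min_leaf[i], min_leaf[j])
    node[i] <- s
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
  }
  structure(list(merge = merge, height = height, n = n, labels = labels),
            class = "ward_dendrogram")
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat("Ward dendrogram:", x$n, "leaves,", length(x$height), "merges; ",
      "total SS =", sum(x$height), "\n")
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k-1 merges; the resulting components are the clusters,
#' numbered by order of first appearance (leaf order).
#'
#' @param dendrogram A `ward_dendrogram`.
#' @param k Number of clusters, 1 <= k <= n.
#' @return Integer vector of cluster labels (named by leaf labels).
#' @export
cut_k <- function(dendrogram, k) {
  n <- dendrogram$n
  if (k < 1L || k > n) stop("k out of range [1, ", n, "]")
  comp <- seq_len(n)
  if (n - k >= 1L) {
    members <- vector("list", n - 1L)
    for (s in seq_len(n - k)) {
      take <- function(v) if (v < 0) -v else members[[v]]
      members[[s]] <- c(take(dendrogram$merge[s, 1]),
                        take(dendrogram$merge[s, 2]))
      comp[members[[s]]] <- min(comp[members[[s]]])
    }
  }
  labs <- match(comp, unique(comp))
  setNames(as.integer(labs), dendrogram$labels)
}

#' Canonical two-cluster naming
#'
#' Names the cluster with the higher MetS fraction "1"; ties are broken by
#' the higher mean 20:3n-6 (DGLA). Without group labels, clusters are named
#' by decreasing size with a warning. Naming is invariant to the input label
#' coding and to subject order.
#'
#' @param assignment Integer cluster labels (two clusters).
#' @param group_labels Character/factor of group labels with level "MetS",
#'   or `NULL`.
#' @param dgla Optional per-subject 20:3n-6 values for the tie-break.
#' @return Relabelled integer vector in {1, 2} with attribute `convention`.
#' @export
canonical_labels <- function(assignment, group_labels = NULL, dgla = NULL) {
  cl <- unique(assignment)
  if (length(cl) != 2L) stop("need exactly two clusters")
  cl <- sort(cl)
  convention <- "mets-fraction"
  if (is.null(group_labels)) {
    warning("no group labels; naming clusters by decreasing size")
    key <- -c(sum(assignment == cl[1]), sum(assignment == cl[2]))
    convention <- "size"
  } else {
    key <- -vapply(cl, function(c0)
      mean(as.character(group_labels[assignment == c0]) == "MetS"), 0)
    if (length(unique(key)) == 1L) {
      if (is.null(dgla)) stop("tied MetS fractions and no dgla for tie-break")
      key <- -vapply(cl, function(c0) mean(dgla[assignment == c0]), 0)
      convention <- "mets-fraction+dgla-tie"
    }
  }
  first <- cl[order(key)][1]
  out <- ifelse(assignment == first, 1L, 2L)
  attr(out, "convention") <- convention
  out
}

#' Cluster-by-group association (Yates-corrected chi-squared)
#'
#' 2x2 table of cluster label against group label, tested with the
#' continuity-corrected Pearson chi-squared statistic
#' sum((|O - E| - 0.5)^2 / E), df = 1.
#'
#' @param assignment Cluster labels (two clusters).
#' @param group_labels Group labels (two levels).
#' @return A `contingency_result` (see [pearson_chi2()]).
#' @export
cluster_group_chi2 <- function(assignment, group_labels) {
  tab <- table(factor(group_labels), factor(assignment))
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 cluster-by-group table")
  pearson_chi2(unclass(matrix(tab, 2, 2, dimnames = dimnames(tab))),
               correction = "yates")
}
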