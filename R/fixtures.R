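#' Bundled reference genotype count tables
#'
#' Genotype counts (AA, Aa, aa per stratum) for the eight-SNP FADS1/FADS2
#' panel in a metabolic-syndrome case-control cohort, as reported for the
#' two FA-profile clusters within the MetS group (`"mets_clusters"`: strata
#' MetS1/MetS2) and for the study groups (`"groups"`: strata MetS, CON,
#' CON1, CON2). These desk-scale fixtures let the contingency machinery be
#' exercised (and its published statistics recomputed) with zero simulation.
#'
#' @param which `"mets_clusters"` or `"groups"`.
#' @return data.frame with columns `snp`, `stratum`, `AA`, `Aa`, `aa`.
#' @export
#' @examples
#' counts <- reference_genotype_counts("mets_clusters")
#' gt <- as.matrix(counts[counts$snp == "rs174537", c("AA", "Aa", "aa")])
#' pearson_chi2(gt, "none")$chi2 # 14.039
reference_genotype_counts <- function(which = c("mets_clusters", "groups")) {
  which <- match.arg(which)
  f <- switch(which,
              mets_clusters = "mets_cluster_genotype_counts.tsv",
              groups = "group_genotype_counts.tsv")
  path <- system.file("extdata", f, package = "fadsmets", mustWork = TRUE)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Reference cluster-by-group subject counts
#'
#' The 2x2 distribution of study subjects over the two FA-profile clusters:
#' rows MetS/CON, columns cluster 1/cluster 2.
#'
#' @return 2x2 integer matrix.
#' @export
reference_cluster_counts <- function() {
  matrix(c(109L, 71L, 57L, 117L), 2, 2,
         dimnames = list(c("MetS", "CON"), c("cluster1", "cluster2")))
}
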