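# End-to-end orchestration: simulate (or load) -> FA metrics -> stepwise
# discriminant selection -> Ward clustering -> per-SNP association scans ->
# haplotype inference, with a JSON run manifest.

#' Standardise and Ward-cluster fatty acid profiles
#'
#' Z-score standardises the selected columns (FAs span two orders of
#' magnitude) unless `standardize = FALSE`, runs [ward_linkage()], cuts at
#' `k` and, when group labels are given, applies the canonical naming of
#' [canonical_labels()].
#'
#' @param cohort Cohort data.frame.
#' @param variables Columns to cluster on.
#' @param k Number of clusters (default 2).
#' @param standardize Z-score the variables first (default TRUE).
#' @param group_labels Optional group labels for canonical naming.
#' @return List with `dendrogram`, `assignment` (integer labels), `variables`.
#' @export
cluster_fa_profiles <- function(cohort, variables, k = 2L,
                                standardize = TRUE, group_labels = NULL) {
  X <- as.matrix(cohort[, variables, drop = FALSE])
  if (standardize) X <- scale(X)
  dend <- ward_linkage(X)
  assign <- cut_k(dend, k)
  if (!is.null(group_labels) && k == 2L) {
    dgla <- if ("20:3n-6" %in% colnames(cohort)) cohort[["20:3n-6"]] else NULL
    assign <- canonical_labels(assign, group_labels, dgla = dgla)
  }
  list(dendrogram = dend, assignment = assign, variables = variables)
}

#' Pipeline configuration
#'
#' Either a generator configuration (synthetic cohort) or input paths
#' (phenotype TSV plus PED/MAP prefix or VCF) must be supplied.
#'
#' @param generator A `generator_config`, or `NULL` when reading files.
#' @param cohort_tsv,ped_prefix,vcf Input paths (file mode).
#' @param f_enter,max_vars Stepwise selection parameters.
#' @param k,standardize Clustering parameters.
#' @param d_prime_threshold Block partition threshold.
#' @param haplo_loci Loci for haplotype inference (default the five-SNP
#'   block).
#' @param n_perm Permutations for the haplotype association.
#' @param seed Seed for the analysis stages (generator has its own).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, cohort_tsv = NULL,
                            ped_prefix = NULL, vcf = NULL,
                            f_enter = 4.0, max_vars = 6L, k = 2L,
                            standardize = TRUE, d_prime_threshold = 0.8,
                            haplo_loci = fads_block_loci(),
                            n_perm = 1000L, seed = 1L) {
  if (is.null(generator) && is.null(cohort_tsv))
    stop("either a generator config or input paths must be given")
  structure(list(generator = generator, cohort_tsv = cohort_tsv,
                 ped_prefix = ped_prefix, vcf = vcf, f_enter = f_enter,
                 max_vars = max_vars, k = k, standardize = standardize,
                 d_prime_threshold = d_prime_threshold,
                 haplo_loci = haplo_loci, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate or load the cohort and genotypes; (2) clinical and FA
#' group comparisons (MetS vs CON) with BH adjustment; (3) stepwise Wilks'
#' lambda variable selection for the MetS/CON discriminant plus its
#' resubstitution accuracy; (4) Ward clustering (k = 2) on the selected FAs,
#' canonical cluster naming and the cluster-by-group Yates chi-squared;
#' (5) per-SNP association scans for the MetS/CON, MetS1/MetS2, CON1/CON2,
#' MetS1/CON1 and MetS2/CON2 contrasts on the genotyped subset; (6) LD
#' matrix, D'-threshold block partition, EM haplotype frequencies on the
#' block and the MetS1-vs-MetS2 haplotype permutation test. All tables are
#' written as TSV under `out_dir` together with a JSON run manifest
#' (config echo, seeds, per-stage row counts, file checksums, warnings).
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))
  files <- character(0)
  emit <- function(x, name) {
    files <<- c(files, write_tsv(x, file.path(out_dir, name)))
    invisible(x)
  }

  # ---- stage 1: simulate or load -------------------------------------------
  if (!is.null(config$generator)) {
    sim <- generate_cohort(config$generator)
    cohort <- sim$cohort; genotypes <- sim$genotypes
    write_cohort_tsv(cohort, file.path(out_dir, "cohort.tsv"))
    write_ped_map(genotypes, file.path(out_dir, "genotypes"),
                  sex = cohort$sex,
                  phenotype = ifelse(cohort$group == "MetS", 2L, 1L))
    write_vcf_minimal(genotypes, file.path(out_dir, "genotypes.vcf"))
    write_truth_json(sim$truth, file.path(out_dir, "truth.json"))
    files <- c(files, file.path(out_dir, c("cohort.tsv", "genotypes.ped",
                                           "genotypes.map", "genotypes.vcf",
                                           "truth.json")))
  } else {
    cohort <- read_cohort_tsv(config$cohort_tsv)
    genotypes <- if (!is.null(config$ped_prefix))
      read_ped_map(config$ped_prefix, snps = fads_snp_panel())
    else if (!is.null(config$vcf)) read_vcf_minimal(config$vcf)
    else NULL
    if (!is.null(genotypes)) {
      common <- intersect(cohort$id, rownames(genotypes$calls))
      if (length(common) == 0L)
        stop("subject-ID mismatch between phenotype and genotype files")
      if (length(common) < nrow(cohort))
        note("only ", length(common), "/", nrow(cohort),
             " subjects have genotypes")
      aligned <- matrix(NA_character_, nrow(cohort), ncol(genotypes$calls))
      aligned[match(common, cohort$id), ] <- genotypes$calls[common, ]
      genotypes <- genotype_matrix(aligned, genotypes$snps, ids = cohort$id)
    }
  }
  if (length(unique(cohort$group)) < 2L)
    stop("cohort contains a single group (", unique(cohort$group)[1],
         "); group contrasts refused")
  set.seed(config$seed)

  # ---- stage 2: FA metrics and clinical comparisons ------------------------
  fa_cols <- intersect(fa_panel(), colnames(cohort))
  if (length(fa_cols) < length(fa_panel()))
    note("FA panel incomplete: ", length(fa_cols), "/18 present")
  derived <- cbind(fa_sums(cohort[, fa_cols, drop = FALSE]),
                   desaturase_indices(cohort[, fa_cols, drop = FALSE]))
  if (all(c("insulin", "glucose") %in% colnames(cohort))) {
    if (!"homa_ir" %in% colnames(cohort))
      cohort$homa_ir <- homa_ir(cohort$insulin, cohort$glucose)
  } else {
    note("insulin and/or glucose column absent; HOMA-IR not computed")
  }
  cohort_full <- cbind(cohort, derived)
  clin_traits <- intersect(c("weight", "waist", "glucose", "insulin", "tag",
                             "homa_ir"), colnames(cohort_full))
  fa_traits <- c(fa_cols, colnames(derived))
  metrics_group <- emit(
    compare_traits(cohort_full, c(clin_traits, fa_traits), "MetS", "CON"),
    "metrics_mets_vs_con.tsv")

  # ---- stage 3: stepwise discriminant selection ----------------------------
  trace <- stepwise_select(cohort_full[, fa_cols, drop = FALSE],
                           cohort_full$group,
                           f_enter = config$f_enter,
                           max_vars = config$max_vars)
  selected <- attr(trace, "selected")
  if (length(selected) == 0L)
    stop("stepwise selection entered no variables; cannot cluster")
  lda <- fit_lda(cohort_full[, fa_cols, drop = FALSE], cohort_full$group,
                 selected)
  emit(as.data.frame(trace), "selection_trace.tsv")

  # ---- stage 4: Ward clustering --------------------------------------------
  clus <- cluster_fa_profiles(cohort_full, selected, k = config$k,
                              standardize = config$standardize,
                              group_labels = cohort_full$group)
  cohort_full$cluster <- clus$assignment
  cg <- cluster_group_chi2(clus$assignment, cohort_full$group)
  emit(data.frame(id = cohort_full$id, cluster = clus$assignment),
       "cluster_assignment.tsv")
  emit(data.frame(step = seq_along(clus$dendrogram$height),
                  merge1 = clus$dendrogram$merge[, 1],
                  merge2 = clus$dendrogram$merge[, 2],
                  height = clus$dendrogram$height),
       "dendrogram_merges.tsv")
  phenotype4 <- paste0(cohort_full$group, cohort_full$cluster)
  metrics_cluster <- emit(
    compare_traits(cohort_full[cohort_full$group == "MetS", ],
                   c(clin_traits, fa_traits), 1L, 2L, group_col = "cluster"),
    "metrics_mets1_vs_mets2.tsv")
  ancova_con <- NULL
  if (all(c("tag", "weight") %in% colnames(cohort_full))) {
    con <- cohort_full[cohort_full$group == "CON", ]
    if (length(unique(con$cluster)) == 2L) {
      ac <- ancova_group_effect(con, "tag", "cluster", "weight")
      ancova_con <- data.frame(trait = "tag", contrast = "CON1 vs CON2",
                               covariate = "weight",
                               estimate = ac$estimate, p_value = ac$p_value,
                               n = ac$n)
      emit(ancova_con, "ancova_con_clusters.tsv")
    }
  }

  # ---- stage 5: per-SNP association scans ----------------------------------
  scans <- NULL
  haplo <- NULL
  if (!is.null(genotypes)) {
    genotyped <- !apply(is.na(genotypes$calls), 1, all)
    contrasts <- list(
      MetS_vs_CON = cohort_full$group,
      MetS1_vs_MetS2 = ifelse(cohort_full$group == "MetS", phenotype4, NA),
      CON1_vs_CON2 = ifelse(cohort_full$group == "CON", phenotype4, NA),
      MetS1_vs_CON1 = ifelse(phenotype4 %in% c("MetS1", "CON1"), phenotype4, NA),
      MetS2_vs_CON2 = ifelse(phenotype4 %in% c("MetS2", "CON2"), phenotype4, NA)
    )
    scans <- lapply(names(contrasts), function(nm) {
      grp <- contrasts[[nm]]
      grp[!genotyped] <- NA
      sc <- association_scan(genotypes, grp, on_error = "na")
      sc$contrast <- nm
      sc
    })
    scans <- do.call(rbind, scans)
    emit(scans, "association_scans.tsv")

    # ---- stage 6: LD, blocks, haplotypes -----------------------------------
    ld <- ld_matrix(genotypes)
    blocks <- block_partition(ld, config$d_prime_threshold)
    emit(data.frame(snp_i = rep(ld$loci, each = length(ld$loci)),
                    snp_j = rep(ld$loci, length(ld$loci)),
                    d_prime = as.vector(ld$d_prime),
                    r2 = as.vector(ld$r2)),
         "ld_matrix.tsv")
    emit(data.frame(block = rep(seq_along(blocks), lengths(blocks)),
                    snp = unlist(blocks)),
         "blocks.tsv")
    hs <- em_haplotype_frequencies(genotypes, config$haplo_loci)
    emit(hs$haplotypes, "haplotype_frequencies.tsv")
    m1m2 <- contrasts$MetS1_vs_MetS2
    m1m2[!genotyped] <- NA
    ok <- !is.na(m1m2)
    if (sum(ok) >= 4L && length(unique(m1m2[ok])) == 2L) {
      sub <- genotype_matrix(genotypes$calls[ok, , drop = FALSE],
                             genotypes$snps,
                             ids = rownames(genotypes$calls)[ok])
      haplo <- haplotype_association(sub, m1m2[ok], config$haplo_loci,
                                     n_perm = config$n_perm,
                                     seed = config$seed)
      emit(haplo, "haplotype_association.tsv")
    } else {
      note("MetS1/MetS2 haplotype contrast skipped: degenerate strata")
    }
  } else {
    note("no genotype input; association and haplotype stages skipped")
    ld <- NULL; blocks <- NULL; hs <- NULL
  }

  # ---- manifest -------------------------------------------------------------
  manifest <- list(
    package_version = as.character(packageVersion("fadsmets")),
    seed = config$seed,
    generator_seed = if (!is.null(config$generator)) config$generator$seed else NULL,
    parameters = list(f_enter = config$f_enter, max_vars = config$max_vars,
                      k = config$k, standardize = config$standardize,
                      d_prime_threshold = config$d_prime_threshold,
                      haplo_loci = config$haplo_loci, n_perm = config$n_perm),
    row_counts = list(
      cohort = nrow(cohort_full),
      genotyped = if (!is.null(genotypes)) sum(genotyped) else 0L,
      selected_variables = length(selected),
      clusters = as.list(table(clus$assignment)),
      scans = if (!is.null(scans)) nrow(scans) else 0L
    ),
    results = list(
      selected = selected,
      lda_accuracy = lda$accuracy,
      cluster_group_chi2 = cg$chi2,
      cluster_group_p = cg$p_raw
    ),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort_full, genotypes = genotypes,
                 metrics_group = metrics_group,
                 metrics_cluster = metrics_cluster,
                 selection = trace, lda = lda, clustering = clus,
                 cluster_group = cg, ancova_con = ancova_con, scans = scans,
                 ld = ld, blocks = blocks, haplotypes = hs,
                 haplotype_association = haplo, manifest = manifest))
}
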