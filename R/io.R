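# Plain-text interchange: cohort phenotype TSV, PLINK PED/MAP text,
# minimal unphased VCF 4.2 (GT only), and the generator truth record as JSON.

#' Write / read the cohort phenotype table
#'
#' One row per subject; FA columns keep their shorthand names (e.g.
#' `18:2n-6`).
#'
#' @param cohort Cohort data.frame.
#' @param path File path.
#' @return `read_cohort_tsv` returns the data.frame.
#' @export
write_cohort_tsv <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Write genotypes as PLINK PED/MAP text
#'
#' PED: family id, individual id, paternal/maternal ids (0), sex code,
#' phenotype code, then two allele columns per SNP (0 0 for missing).
#' MAP: chromosome, SNP id, genetic distance (0), position.
#'
#' @param genotypes A `genotype_matrix`.
#' @param prefix Output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @param sex,phenotype Optional vectors for the PED columns (defaults 0).
#' @return Invisibly, the two file paths.
#' @export
write_ped_map <- function(genotypes, prefix, sex = NULL, phenotype = NULL) {
  calls <- genotypes$calls
  n <- nrow(calls)
  sexc <- if (is.null(sex)) rep(0L, n) else ifelse(sex == "M", 1L, 2L)
  phen <- if (is.null(phenotype)) rep(0L, n) else phenotype
  al <- matrix("0", n, 2L * ncol(calls))
  for (j in seq_len(ncol(calls))) {
    ok <- !is.na(calls[, j])
    al[ok, 2L * j - 1L] <- substring(calls[ok, j], 1L, 1L)
    al[ok, 2L * j] <- substring(calls[ok, j], 3L, 3L)
  }
  ped <- cbind(rownames(calls), rownames(calls), "0", "0", sexc, phen, al)
  write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  map <- genotypes$snps[, c("chrom", "snp")]
  map$cm <- 0
  map$pos <- genotypes$snps$pos
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Read PLINK PED/MAP text into a genotype matrix
#'
#' Allele `0` is treated as missing. Major/minor alleles are taken from the
#' supplied SNP metadata when given, otherwise recomputed from the data
#' (most frequent allele = major).
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @param snps Optional SNP metadata (as from [fads_snp_panel()]).
#' @return A `genotype_matrix`.
#' @export
read_ped_map <- function(prefix, snps = NULL) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp", "cm", "pos"))
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  L <- nrow(map)
  if (ncol(ped) != 6L + 2L * L)
    stop("PED/MAP mismatch: expected ", 6L + 2L * L, " PED columns")
  ids <- ped[[2]]
  calls <- matrix(NA_character_, nrow(ped), L)
  observed_major <- observed_minor <- character(L)
  for (j in seq_len(L)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    ok <- a1 != "0" & a2 != "0"
    calls[ok, j] <- paste(pmin(a1[ok], a2[ok]), pmax(a1[ok], a2[ok]), sep = "/")
    tab <- sort(table(c(a1[ok], a2[ok])), decreasing = TRUE)
    observed_major[j] <- names(tab)[1]
    observed_minor[j] <- if (length(tab) > 1L) names(tab)[2] else NA_character_
  }
  if (is.null(snps)) {
    snps <- data.frame(snp = map$snp, chrom = as.character(map$chrom),
                       pos = map$pos, major = observed_major,
                       minor = observed_minor, gene = NA_character_,
                       stringsAsFactors = FALSE)
  } else {
    snps <- snps[match(map$snp, snps$snp), ]
    if (anyNA(snps$snp)) stop("MAP SNP missing from supplied metadata")
  }
  genotype_matrix(calls, snps, ids = ids)
}

#' Write genotypes as a minimal unphased VCF 4.2
#'
#' Biallelic sites, GT-only FORMAT, `0/1`-style unphased calls, `./.` for
#' missing; REF = major allele, ALT = minor allele.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf_minimal <- function(genotypes, path) {
  snps <- genotypes$snps
  calls <- genotypes$calls
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=fadsmets",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(calls)), collapse = "\t")),
             con)
  for (j in seq_len(ncol(calls))) {
    gt <- rep("./.", nrow(calls))
    ok <- !is.na(calls[, j])
    dose <- (substring(calls[ok, j], 1, 1) == snps$minor[j]) +
      (substring(calls[ok, j], 3, 3) == snps$minor[j])
    gt[ok] <- c("0/0", "0/1", "1/1")[dose + 1L]
    writeLines(paste(c(snps$chrom[j], snps$pos[j], snps$snp[j],
                       snps$major[j], snps$minor[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal GT-only VCF into a genotype matrix
#'
#' Understands unphased or phased diploid GT codes on biallelic sites.
#'
#' @param path VCF path (plain text).
#' @param gene Optional gene labels per site.
#' @return A `genotype_matrix`.
#' @export
read_vcf_minimal <- function(path, gene = NA_character_) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(body) < 2L) stop("VCF has no variant records")
  ids <- header[-(1:9)]
  recs <- strsplit(body[-1], "\t", fixed = TRUE)
  L <- length(recs)
  calls <- matrix(NA_character_, length(ids), L)
  snps <- data.frame(snp = character(L), chrom = character(L), pos = integer(L),
                     major = character(L), minor = character(L),
                     gene = gene, stringsAsFactors = FALSE)
  for (j in seq_len(L)) {
    r <- recs[[j]]
    snps$chrom[j] <- r[1]; snps$pos[j] <- as.integer(r[2])
    snps$snp[j] <- r[3]; snps$major[j] <- r[4]; snps$minor[j] <- r[5]
    gt <- sub(":.*", "", r[-(1:9)])
    gt <- gsub("|", "/", gt, fixed = TRUE)
    dose <- ifelse(gt %in% c("0/0"), 0L,
                   ifelse(gt %in% c("0/1", "1/0"), 1L,
                          ifelse(gt %in% c("1/1"), 2L, NA_integer_)))
    A <- r[4]; a <- r[5]
    cls <- c(paste(sort(c(A, A)), collapse = "/"),
             paste(sort(c(A, a)), collapse = "/"),
             paste(sort(c(a, a)), collapse = "/"))
    calls[, j] <- ifelse(is.na(dose), NA_character_, cls[dose + 1L])
  }
  snps <- snps[, c("snp", "chrom", "pos", "major", "minor", "gene")]
  genotype_matrix(calls, snps, ids = ids)
}

#' Write the generator truth record as JSON
#'
#' @param truth The `truth` element of [generate_cohort()] output.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(
    hap1 = truth$hap1, hap2 = truth$hap2, cluster = truth$cluster,
    config = list(
      n_mets = truth$config$n_mets, n_con = truth$config$n_con,
      n_genotyped = truth$config$n_genotyped, seed = truth$config$seed,
      haplotype_pool = truth$config$haplotype_pool,
      cluster_logit = truth$config$cluster_logit,
      group_given_cluster = as.list(truth$config$group_given_cluster)
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
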