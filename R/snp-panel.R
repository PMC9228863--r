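#' FADS1/FADS2 SNP panel metadata
#'
#' The eight biallelic SNPs of the FADS1-FADS2 region on chromosome 11
#' analysed by this package, ordered by map position. `major`/`minor` carry
#' the declared major (A) and minor (a) allele; the first five loci
#' (rs174537, rs174545, rs174546, rs968567, rs174570) form the canonical
#' haplotype block used for multi-locus inference.
#'
#' @return A data.frame with columns `snp`, `chrom`, `pos`, `major`, `minor`,
#'   `gene`, one row per SNP, ordered by `pos`.
#' @export
#' @examples
#' fads_snp_panel()
fads_snp_panel <- function() {
  data.frame(
    snp   = c("rs174537", "rs174545", "rs174546", "rs968567",
              "rs174570", "rs174575", "rs174602", "rs174589"),
    chrom = "11",
    pos   = c(61785208L, 61786870L, 61787355L, 61809636L,
              61828092L, 61834544L, 61847102L, 61856942L),
    major = c("G", "G", "G", "C", "C", "C", "T", "C"),
    minor = c("T", "C", "A", "T", "T", "G", "C", "G"),
    gene  = c("FADS1", "FADS1", "FADS1", "FADS2",
              "FADS2", "FADS2", "FADS2", "FADS2"),
    stringsAsFactors = FALSE
  )
}

#' SNP ids of the canonical five-locus haplotype block
#' @return Character vector of the five block SNP ids in map order.
#' @export
fads_block_loci <- function() {
  c("rs174537", "rs174545", "rs174546", "rs968567", "rs174570")
}

#' The 18-FA plasma phospholipid panel
#'
#' Shorthand notation: carbons:double bonds, n-position of the first double
#' bond from the methyl end.
#'
#' @return Character vector of the 18 fatty acid names.
#' @export
fa_panel <- function() {
  c("14:0", "16:0", "16:1n-9", "16:1n-7", "18:0", "18:1n-9", "18:1n-7",
    "18:2n-6", "18:3n-6", "18:3n-3", "20:2n-6", "20:3n-6", "20:4n-6",
    "20:5n-3", "22:4n-6", "22:5n-6", "22:5n-3", "22:6n-3")
}
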