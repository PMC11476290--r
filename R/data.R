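# Shipped reference tables: a published catalog of high-confidence
# A-to-I miRNA editing sites reported in human lung tissue, and the
# reported composition of the high-confidence lung isomiR/miRNA catalog.
# Both serve as worked examples for the catalog-summary statistics.

#' Published lung A-to-I editing-site catalog
#'
#' Sixteen high-confidence A-to-I edited isomiRs reported in human lung
#' tissue: canonical miRNA, 5' shift, 0-based edited position in isomiR
#' coordinates, and the nucleotides immediately 5' and 3' of the edited
#' adenosine (drawn from the precursor where the neighbour lies outside
#' the mature sequence).
#'
#' @return data.table with columns `mirna`, `five_prime_shift`,
#'   `edited_position`, `adjacent_5p`, `adjacent_3p`.
#' @export
#' @examples
#' summarize_catalog(lung_editing_catalog())
lung_editing_catalog <- function() {
  data.table::fread(system.file("extdata", "lung_editing_sites.tsv",
                                package = "isomirome"))
}

#' Reported composition of the high-confidence lung catalog
#'
#' Numbers of high-confidence entries per class in the published lung
#' catalog: A-to-I edited, 5' shifted, 3' adenylated and 3' uridylated
#' isomiRs, plus miRNAs.
#'
#' @return data.table with columns `type`, `n`.
#' @export
lung_catalog_counts <- function() {
  data.table::fread(system.file("extdata", "lung_catalog_counts.tsv",
                                package = "isomirome"))
}

#' IsomiR share of unique high-confidence sequences
#'
#' Fraction (percent) of a catalog's unique high-confidence entries that
#' are isomiRs rather than canonical miRNAs.
#'
#' @param counts a table as returned by [lung_catalog_counts()].
#' @return percentage of entries that are isomiRs.
#' @export
isomir_sequence_share <- function(counts = lung_catalog_counts()) {
  ct <- data.table::as.data.table(counts)
  n_iso <- sum(ct$n[ct$type != "miRNA"])
  100 * n_iso / sum(ct$n)
}
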