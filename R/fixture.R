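# Packaged genotype fixture: the per-individual allele listing of the
# 32-individual study cohort, hand-transcribed. Guarded by an md5 checksum
# and by cross-checking row sums against the transcription's printed totals.

.TABLE1_MD5 <- "1c972ff3fd49667a969b3f6bdc4fff59"

#' Load the packaged 32-individual genotype fixture
#'
#' Returns the transcribed individuals-by-alleles presence table: 32
#' individuals (19 east, 11 north, 2 admixed), 11 functional alleles
#' (DRB*01..DRB*11) and 3 pseudogenes (DRB*PS01..DRB*PS03). The file's md5
#' checksum and the per-row functional/pseudogene totals recorded at
#' transcription time are verified on load.
#'
#' @return A `genotype_matrix`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_genotypes.tsv", package = "drbdiv",
                      mustWork = TRUE)
  sum_now <- unname(tools::md5sum(path))
  if (!identical(sum_now, .TABLE1_MD5)) {
    stop("checksum mismatch on genotype fixture (got ", sum_now, ")")
  }
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  allele_cols <- grep("^DRB\\*", names(tab), value = TRUE)
  fn_cols <- allele_cols[!grepl("PS", allele_cols)]
  ps_cols <- allele_cols[grepl("PS", allele_cols)]
  if (!all(rowSums(tab[fn_cols]) == tab$total_functional) ||
      !all(rowSums(tab[ps_cols]) == tab$total_pseudogene)) {
    stop("fixture row sums disagree with transcribed totals")
  }
  presence <- as.matrix(tab[allele_cols]) > 0
  rownames(presence) <- as.character(tab$individual_id)
  status <- stats::setNames(
    ifelse(grepl("PS", allele_cols), "pseudogene", "functional"), allele_cols)
  genotype_matrix(presence,
                  stats::setNames(tab$subpop, rownames(presence)),
                  status)
}
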