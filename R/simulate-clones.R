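# Clone sets with PCR artifacts. Each clone is one sequenced plasmid insert:
# a faithful copy of one of the individual's alleles, a copy with point
# errors, or a single-crossover chimera of two alleles from the same
# individual. Point errors are uniform base substitutions; indels are not
# simulated as artifacts (observed pseudogene indels are germline).

#' Simulate plasmid clone sets from cohort ground truth
#'
#' Clone counts per individual are Poisson(`mean_clones`) with a minimum of
#' one. A chimera joins the head of one parental allele to the tail of
#' another at a uniformly drawn crossover point; if an individual carries
#' only one allele the chimera is downgraded to a faithful clone and logged.
#' Provenance (`faithful` / `point_error` / `chimera`) partitions the clones;
#' a chimera that also picks up point errors stays `chimera`.
#'
#' @param truth A `cohort_truth`.
#' @param mean_clones Mean clones per individual (> 0).
#' @param error_rate Per-base substitution probability in `[0, 1]`.
#' @param chimera_rate Per-clone chimera probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `clone_set` data.frame (individual_id, clone_id, seq,
#'   provenance) with attribute `downgraded_chimeras` (log of chimera
#'   requests on single-allele individuals).
#' @export
simulate_clones <- function(truth, mean_clones = 26.9, error_rate = 0.001,
                            chimera_rate = 0.02, seed = NULL) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (mean_clones <= 0) stop("mean_clones must be > 0")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (chimera_rate < 0 || chimera_rate > 1) stop("chimera_rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  pool_seqs <- c(truth$pool$functional, truth$pool$pseudogene)
  out <- vector("list", nrow(truth$individuals))
  downgraded <- character(0)
  for (r in seq_len(nrow(truth$individuals))) {
    id <- truth$individuals$individual_id[r]
    alleles <- truth$alleles[[id]]
    seqs <- pool_seqs[alleles]
    n <- max(1L, stats::rpois(1L, mean_clones))
    clone_seq <- character(n)
    provenance <- character(n)
    for (k in seq_len(n)) {
      is_chimera <- stats::runif(1) < chimera_rate
      if (is_chimera && length(seqs) < 2L) {
        downgraded <- c(downgraded, sprintf("%s|clone%d", id, k))
        is_chimera <- FALSE
      }
      if (is_chimera) {
        par <- sample(length(seqs), 2L)
        s1 <- seqs[[par[1]]]; s2 <- seqs[[par[2]]]
        x <- sample.int(min(nchar(s1), nchar(s2)) - 1L, 1L)
        s <- paste0(substr(s1, 1L, x), substr(s2, x + 1L, nchar(s2)))
        prov <- "chimera"
      } else {
        s <- seqs[[sample(length(seqs), 1L)]]
        prov <- "faithful"
      }
      if (error_rate > 0) {
        chars <- strsplit(s, "")[[1]]
        hit <- which(stats::runif(length(chars)) < error_rate)
        if (length(hit)) {
          for (pos in hit) {
            chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1L)
          }
          s <- paste0(chars, collapse = "")
          if (prov == "faithful") prov <- "point_error"
        }
      }
      clone_seq[k] <- s
      provenance[k] <- prov
    }
    out[[r]] <- data.frame(individual_id = id,
                           clone_id = sprintf("clone%d", seq_len(n)),
                           seq = clone_seq, provenance = provenance,
                           stringsAsFactors = FALSE)
  }
  clones <- as_clone_set(do.call(rbind, out))
  attr(clones, "downgraded_chimeras") <- downgraded
  clones
}

#' Write clone provenance as TSV
#'
#' @param clones A `clone_set` with a provenance column.
#' @param path Output path.
#' @export
write_provenance_tsv <- function(clones, path) {
  if (is.null(clones$provenance)) stop("clone set has no provenance column")
  utils::write.table(
    clones[, c("individual_id", "clone_id", "provenance")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
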