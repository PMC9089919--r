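# Synthetic allele pools. The generator emulates a clone-sequencing study of
# a multi-locus MHC class II DRB exon 2 system: a catalog of divergent
# functional alleles over an 80-codon amplicon that starts mid-codon, plus
# pseudogene alleles each carrying a single germline one-base deletion.

#' Simulate a pool of functional and pseudogene alleles
#'
#' Functional alleles are generated from a random stop-free root codon
#' sequence by placing substitutions independently on each allele's branch of
#' a star phylogeny (transition:transversion weighting `kappa`, with
#' stop-avoidance resampling), calibrated so that the mean pairwise
#' nucleotide p-distance approximates `target_divergence`. Pseudogenes are
#' derived from functional alleles by deleting exactly one base.
#'
#' @param n_functional Number of functional alleles (>= 1).
#' @param n_pseudo Number of pseudogene alleles.
#' @param n_codons Number of complete codons in the amplicon (default 80).
#' @param frame_offset Leading nucleotides before the first complete codon
#'   (default 2; amplicon length is `3 * n_codons + frame_offset`).
#' @param target_divergence Target mean pairwise p-distance between
#'   functional alleles (0..0.5).
#' @param kappa Transition/transversion rate ratio used when substituting.
#' @param seed Integer seed; all randomness is derived from it.
#' @return An `allele_pool`: list with `functional` and `pseudogene` named
#'   sequence vectors, `n_codons`, `frame_offset`, `root`, and `deletions`
#'   (per pseudogene: parent allele and deleted position).
#' @export
simulate_allele_pool <- function(n_functional, n_pseudo = 0L, n_codons = 80L,
                                 frame_offset = 2L, target_divergence = 0.15,
                                 kappa = 2, seed = NULL) {
  if (n_functional < 1L) stop("n_functional must be >= 1")
  if (target_divergence < 0 || target_divergence > 0.5) {
    stop("target_divergence must be in [0, 0.5]")
  }
  if (target_divergence == 0 && n_functional > 1L) {
    stop("unsatisfiable: divergence 0 with more than one functional allele ",
         "cannot yield unique sequences")
  }
  if (n_pseudo > 0L && n_functional < 1L) stop("pseudogenes need a functional parent")
  if (!is.null(seed)) set.seed(seed)

  L <- 3L * n_codons + frame_offset
  root <- paste0(
    paste0(sample(c("A", "C", "G", "T"), frame_offset, replace = TRUE), collapse = ""),
    paste0(random_sense_codons(n_codons), collapse = ""))

  # Substitutions per allele branch: with k distinct mutated positions per
  # allele, expected pairwise p-distance is (2k - (4/3) k^2 / L) / L
  # (disjoint positions always differ; shared positions differ w.p. ~2/3).
  # Solve the quadratic for k/L.
  k <- 0L
  if (n_functional > 1L) {
    p <- target_divergence
    x <- (2 - sqrt(max(0, 4 - (16 / 3) * p))) / (8 / 3)
    k <- max(1L, as.integer(round(x * L)))
  }

  functional <- character(n_functional)
  for (i in seq_len(n_functional)) {
    functional[i] <- .mutate_sequence(root, k, kappa, frame_offset)
  }
  # enforce uniqueness by adding substitutions to duplicates
  guard <- 0L
  while (anyDuplicated(functional) && guard < 1000L) {
    d <- which(duplicated(functional))[1]
    functional[d] <- .mutate_sequence(functional[d], 1L, kappa, frame_offset)
    guard <- guard + 1L
  }
  if (anyDuplicated(functional)) stop("could not generate unique functional alleles")
  names(functional) <- sprintf("A%02d", seq_len(n_functional))

  pseudogene <- character(n_pseudo)
  deletions <- data.frame(pseudogene = character(0), parent = character(0),
                          position = integer(0), stringsAsFactors = FALSE)
  if (n_pseudo > 0L) {
    for (j in seq_len(n_pseudo)) {
      repeat {
        parent <- sample(names(functional), 1L)
        pos <- sample.int(L, 1L)
        del <- paste0(substr(functional[[parent]], 1L, pos - 1L),
                      substr(functional[[parent]], pos + 1L, L))
        if (!del %in% pseudogene && !del %in% functional) break
      }
      pseudogene[j] <- del
      deletions <- rbind(deletions, data.frame(
        pseudogene = sprintf("PS%02d", j), parent = parent, position = pos,
        stringsAsFactors = FALSE))
    }
    names(pseudogene) <- sprintf("PS%02d", seq_len(n_pseudo))
  }

  pool <- structure(list(functional = functional, pseudogene = pseudogene,
                         n_codons = n_codons, frame_offset = frame_offset,
                         root = root, deletions = deletions),
                    class = "allele_pool")
  validate_allele_pool(pool)
  pool
}

# mutate k distinct positions; within codons, resample the base if the change
# would create an in-frame stop codon
.mutate_sequence <- function(seq, k, kappa, frame_offset) {
  if (k == 0L) return(seq)
  tb <- .codon_tables()
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  positions <- sample.int(L, min(k, L))
  for (pos in positions) {
    old <- chars[pos]
    cands <- setdiff(tb$bases, old)
    w <- ifelse(tb$purine[cands] == tb$purine[[old]], kappa, 1)
    ok <- FALSE
    for (try in seq_len(12L)) {
      new <- sample(cands, 1L, prob = w)
      chars[pos] <- new
      if (pos <= frame_offset) { ok <- TRUE; break }
      ci <- (pos - frame_offset - 1L) %/% 3L  # 0-based codon index
      st <- frame_offset + 3L * ci + 1L
      if (st + 2L > L) { ok <- TRUE; break }  # incomplete trailing codon
      cd <- paste0(chars[st:(st + 2L)], collapse = "")
      if (!is_stop_codon(cd)) { ok <- TRUE; break }
      chars[pos] <- old
    }
    if (!ok) chars[pos] <- old
  }
  paste0(chars, collapse = "")
}

#' Validate allele pool invariants
#'
#' Checks uniqueness, stop-free reading frames of functional alleles, and
#' that each pseudogene is one deleted base away from some functional allele.
#'
#' @param pool An `allele_pool`.
#' @return Invisibly, the pool; errors on violation.
#' @export
validate_allele_pool <- function(pool) {
  stopifnot(inherits(pool, "allele_pool"))
  L <- 3L * pool$n_codons + pool$frame_offset
  if (any(nchar(pool$functional) != L)) stop("functional allele with wrong length")
  if (anyDuplicated(pool$functional)) stop("duplicate functional alleles")
  for (a in pool$functional) {
    if (any(is_stop_codon(inframe_codons(a, pool$frame_offset)))) {
      stop("functional allele contains in-frame stop codon")
    }
  }
  for (ps in pool$pseudogene) {
    if (nchar(ps) != L - 1L) stop("pseudogene with wrong length")
    if (!any(vapply(pool$functional, .is_one_deletion_of, logical(1), shorter = ps))) {
      stop("pseudogene is not a one-base deletion of any functional allele")
    }
  }
  invisible(pool)
}

# TRUE iff `shorter` equals `longer` with exactly one base removed
.is_one_deletion_of <- function(longer, shorter) {
  if (nchar(shorter) != nchar(longer) - 1L) return(FALSE)
  a <- strsplit(longer, "")[[1]]
  b <- strsplit(shorter, "")[[1]]
  n <- length(b)
  pref <- 0L
  while (pref < n && a[pref + 1L] == b[pref + 1L]) pref <- pref + 1L
  identical(a[-(pref + 1L)], b)
}

#' Mean pairwise nucleotide p-distance of the functional alleles
#'
#' @param pool An `allele_pool`.
#' @return Mean proportion of differing positions over all unordered pairs.
#' @export
pool_mean_p_distance <- function(pool) {
  seqs <- pool$functional
  if (length(seqs) < 2L) return(0)
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  pairs <- utils::combn(nrow(mat), 2L)
  mean(apply(pairs, 2L, function(ij) mean(mat[ij[1], ] != mat[ij[2], ])))
}
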