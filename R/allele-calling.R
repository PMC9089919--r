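# Allele calling: collapse clones to candidate sequences, validate with the
# two-detection rule (a sequence must be seen at least twice: twice in one
# individual, or once each in at least two individuals; singletons are
# discarded as likely PCR chimeras/errors), classify open reading frames,
# name alleles and build the genotype matrix.

#' Collapse a clone set into candidate sequences
#'
#' One candidate per distinct sequence, with per-individual clone support.
#'
#' @param clones A `clone_set`.
#' @return List of candidates, each `list(seq, support, total_support)` where
#'   `support` is a named integer vector (individual -> clone count).
#' @export
collapse_clones <- function(clones) {
  clones <- as_clone_set(clones)
  split_ind <- split(clones$individual_id, clones$seq)
  # preserve first-observation order of sequences
  first_seen <- tapply(seq_len(nrow(clones)), clones$seq, min)
  ord <- names(sort(first_seen))
  lapply(ord, function(s) {
    tab <- table(split_ind[[s]])
    support <- stats::setNames(as.integer(tab), names(tab))
    list(seq = s, support = support, total_support = sum(support))
  })
}

#' Apply the two-detection validation rule to candidates
#'
#' A candidate is validated iff its total clone support is at least 2
#' (twice in one individual, or once each in two or more individuals).
#' Single, unique sequences are rejected.
#'
#' @param candidates Output of [collapse_clones()].
#' @return List with `validated` and `rejected_singletons`, a partition of
#'   the input.
#' @export
validate_candidates <- function(candidates) {
  ok <- vapply(candidates, function(cd) cd$total_support >= 2L, logical(1))
  list(validated = candidates[ok], rejected_singletons = candidates[!ok])
}

#' Classify a sequence as functional allele or pseudogene
#'
#' A sequence is functional iff it has the expected amplicon length and its
#' reading frame (after `frame_offset` leading nucleotides) contains no stop
#' codon. Any length deviation within 6 nt marks an indel (pseudogene);
#' larger deviations are rejected as non-target amplicons. When reference
#' functional alleles are supplied, an indel is localized by global pairwise
#' alignment (match +1, mismatch -1, gap -2) against the closest reference;
#' only the length test decides status.
#'
#' @param seq DNA string.
#' @param n_codons Number of complete codons in a functional amplicon.
#' @param frame_offset Leading nucleotides before the first complete codon.
#' @param expected_length Expected functional amplicon length
#'   (default `3 * n_codons + frame_offset`).
#' @param reference_alleles Optional named character vector of functional
#'   allele sequences used to localize indels.
#' @return List with `status` ("functional" or "pseudogene") and
#'   `orf_report` (length, frame_offset, indel_detected,
#'   premature_stop_positions, and `indel_position` when localized).
#' @export
classify_sequence <- function(seq, n_codons = 80L, frame_offset = 2L,
                              expected_length = 3L * n_codons + frame_offset,
                              reference_alleles = NULL) {
  len <- nchar(seq)
  if (abs(len - expected_length) > 6L) {
    stop("length deviation > 6 nt (", len, " vs expected ", expected_length,
         "): rejected as non-target amplicon")
  }
  codons <- inframe_codons(seq, frame_offset)
  stops <- which(is_stop_codon(codons))
  indel <- len != expected_length
  status <- if (!indel && length(stops) == 0L) "functional" else "pseudogene"
  report <- list(length = len, frame_offset = frame_offset,
                 indel_detected = indel,
                 premature_stop_positions = as.integer(stops))
  if (indel && !is.null(reference_alleles) && length(reference_alleles)) {
    report$indel_position <- .locate_indel(seq, reference_alleles)
  }
  list(status = status, orf_report = report)
}

# localize an indel by aligning against the closest reference allele
.locate_indel <- function(seq, reference_alleles) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  best <- NULL
  best_score <- -Inf
  for (ref in reference_alleles) {
    al <- Biostrings::pairwiseAlignment(seq, ref, substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = 2,
                                        type = "global")
    if (Biostrings::score(al) > best_score) {
      best_score <- Biostrings::score(al)
      best <- al
    }
  }
  if (is.null(best)) return(NA_integer_)
  pat <- strsplit(as.character(Biostrings::alignedPattern(best)), "")[[1]]
  gap <- which(pat == "-")
  if (length(gap)) gap[1] else NA_integer_
}

#' Name validated alleles
#'
#' Functional alleles are numbered `<prefix>-DRB*01` onwards by decreasing
#' carrier count (ties broken by first-observation order); pseudogenes get
#' `<prefix>-DRB*PS01` onwards by the same rule.
#'
#' @param validated List of validated candidates, each carrying `seq`,
#'   `support` and a `status` field ("functional"/"pseudogene").
#' @param prefix Species prefix (default "Gugu").
#' @return The input list with a `name` field added, reordered so functional
#'   alleles come first in naming order.
#' @export
name_alleles <- function(validated, prefix = "Gugu") {
  status <- vapply(validated, `[[`, "", "status")
  carriers <- vapply(validated, function(cd) length(cd$support), integer(1))
  order_within <- function(sel, fmt) {
    ids <- which(sel)
    ids <- ids[order(-carriers[ids], seq_along(ids))]
    for (i in seq_along(ids)) validated[[ids[i]]]$name <<- sprintf(fmt, prefix, i)
    ids
  }
  fi <- order_within(status == "functional", "%s-DRB*%02d")
  pi_ <- order_within(status == "pseudogene", "%s-DRB*PS%02d")
  out <- validated[c(fi, pi_)]
  nm <- vapply(out, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("allele naming produced duplicates")
  out
}

#' Build the individuals-by-alleles genotype matrix
#'
#' Presence is TRUE iff the allele was observed in at least one clone of the
#' individual and the allele is globally validated.
#'
#' @param alleles Named character vector of validated allele sequences with a
#'   `status` attribute (named character vector functional/pseudogene).
#' @param clones The `clone_set` the alleles were called from.
#' @param labels Named character vector individual -> subpopulation
#'   (north/east/admixed).
#' @return A `genotype_matrix`.
#' @export
build_genotype_matrix <- function(alleles, clones, labels) {
  clones <- as_clone_set(clones)
  inds <- unique(clones$individual_id)
  missing_lab <- setdiff(inds, names(labels))
  if (length(missing_lab)) {
    stop("individual(s) without subpopulation label: ",
         paste(missing_lab, collapse = ", "))
  }
  status <- attr(alleles, "status")
  if (is.null(status)) stop("alleles must carry a 'status' attribute")
  presence <- matrix(FALSE, length(inds), length(alleles),
                     dimnames = list(inds, names(alleles)))
  seq_to_allele <- stats::setNames(names(alleles), unname(alleles))
  hit <- seq_to_allele[clones$seq]
  keep <- !is.na(hit)
  if (any(keep)) {
    presence[cbind(match(clones$individual_id[keep], inds), match(hit[keep], names(alleles)))] <- TRUE
  }
  empty <- rownames(presence)[rowSums(presence) == 0L]
  if (length(empty)) {
    warning("individual(s) with no validated allele: ", paste(empty, collapse = ", "))
  }
  genotype_matrix(presence, labels[inds], status[names(alleles)])
}

#' Construct a genotype matrix object
#'
#' @param presence Logical matrix, individuals x alleles.
#' @param subpop Named character vector individual -> subpopulation, labels
#'   from north/east/admixed.
#' @param status Named character vector allele -> functional/pseudogene.
#' @return A `genotype_matrix`: list(presence, subpop, status).
#' @export
genotype_matrix <- function(presence, subpop, status) {
  stopifnot(is.matrix(presence), is.logical(presence))
  if (!all(rownames(presence) %in% names(subpop))) stop("individuals lack labels")
  bad <- setdiff(unique(unname(subpop)), c("north", "east", "admixed"))
  if (length(bad)) stop("unknown subpopulation label(s): ", paste(bad, collapse = ", "))
  if (!setequal(colnames(presence), names(status))) {
    stop("allele status names must match presence columns")
  }
  structure(list(presence = presence,
                 subpop = subpop[rownames(presence)],
                 status = status[colnames(presence)]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$presence), "individuals x",
      ncol(x$presence), "alleles (",
      sum(x$status == "functional"), "functional,",
      sum(x$status == "pseudogene"), "pseudogene )\n")
  cat("subpopulations:", paste(sprintf("%s=%d", names(table(x$subpop)),
                                       table(x$subpop)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a genotype matrix as TSV (0/1 presence)
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- data.frame(individual_id = rownames(gm$presence),
                   subpop = unname(gm$subpop),
                   gm$presence + 0L, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# status\t\t", paste(gm$status, collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix TSV written by [write_genotype_tsv()]
#'
#' @param path Input path.
#' @return A `genotype_matrix`.
#' @export
read_genotype_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# status")) stop("not a genotype matrix TSV: ", path)
  status_vals <- strsplit(first, "\t", fixed = TRUE)[[1]][-(1:2)]
  tab <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                           stringsAsFactors = FALSE)
  presence <- as.matrix(tab[, -(1:2), drop = FALSE]) > 0
  rownames(presence) <- tab$individual_id
  genotype_matrix(presence,
                  stats::setNames(tab$subpop, tab$individual_id),
                  stats::setNames(status_vals, colnames(presence)))
}

#' Run the full allele-calling stage on a clone set
#'
#' Collapse, validate, classify (dropping non-target lengths), name, and
#' assemble the genotype matrix.
#'
#' @param clones A `clone_set`.
#' @param labels Named character vector individual -> subpopulation.
#' @param n_codons,frame_offset,expected_length Classifier settings.
#' @param prefix Allele name prefix.
#' @return List with `alleles` (named sequences, `status` attribute),
#'   `calls` (per-allele classification reports), `genotypes`
#'   (genotype_matrix), `rejected_singletons`, `rejected_length` counts.
#' @export
call_alleles <- function(clones, labels, n_codons = 80L, frame_offset = 2L,
                         expected_length = 3L * n_codons + frame_offset,
                         prefix = "Gugu") {
  candidates <- collapse_clones(clones)
  val <- validate_candidates(candidates)
  kept <- list()
  rejected_length <- 0L
  refs <- vapply(val$validated, `[[`, "", "seq")
  refs <- refs[nchar(refs) == expected_length]
  for (cd in val$validated) {
    cl <- tryCatch(
      classify_sequence(cd$seq, n_codons, frame_offset, expected_length,
                        reference_alleles = refs),
      error = function(e) NULL)
    if (is.null(cl)) { rejected_length <- rejected_length + 1L; next }
    cd$status <- cl$status
    cd$orf_report <- cl$orf_report
    kept[[length(kept) + 1L]] <- cd
  }
  named <- name_alleles(kept, prefix = prefix)
  alleles <- stats::setNames(vapply(named, `[[`, "", "seq"),
                             vapply(named, `[[`, "", "name"))
  attr(alleles, "status") <- stats::setNames(
    vapply(named, `[[`, "", "status"), names(alleles))
  gm <- build_genotype_matrix(alleles, clones, labels)
  list(alleles = alleles, calls = named, genotypes = gm,
       rejected_singletons = val$rejected_singletons,
       rejected_length = rejected_length)
}
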