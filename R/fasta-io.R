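# FASTA and table I/O. Sequence files go through Biostrings; the light
# pre-validation exists only to give line-level error messages that
# readDNAStringSet does not.

#' Read a FASTA file into a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case DNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA: first record has no '>' header (line ",
         nonblank[1], " of ", path, ")")
  }
  set <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(set) == 0L)) {
    stop("malformed FASTA: empty sequence record in ", path)
  }
  ids <- names(set)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' Output is deterministic: same input, byte-identical file.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

#' Parse a clone FASTA header
#'
#' Clone headers follow `IND<id>|clone<k>`.
#'
#' @param header Character vector of headers.
#' @return data.frame with columns `individual_id`, `clone_id`.
#' @export
parse_clone_header <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed clone header(s): ", paste(header[bad], collapse = ", "),
         " (expected 'IND<id>|clone<k>')")
  }
  data.frame(individual_id = vapply(parts, `[[`, "", 1L),
             clone_id = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Read a clone FASTA into a clone set
#'
#' @param path FASTA path with headers `IND<id>|clone<k>`.
#' @return A `clone_set` data.frame: individual_id, clone_id, seq.
#' @export
read_clone_fasta <- function(path) {
  seqs <- read_fasta(path)
  meta <- parse_clone_header(names(seqs))
  cs <- data.frame(meta, seq = unname(seqs), stringsAsFactors = FALSE)
  as_clone_set(cs)
}

#' Write a clone set as FASTA
#'
#' @param clones A `clone_set`.
#' @param path Output path.
#' @export
write_clone_fasta <- function(clones, path) {
  clones <- as_clone_set(clones)
  seqs <- clones$seq
  names(seqs) <- paste0(clones$individual_id, "|", clones$clone_id)
  write_fasta(seqs, path)
}

#' Coerce a data.frame to a clone set
#'
#' @param x data.frame with columns individual_id, clone_id, seq.
#' @return x with class `clone_set`, after validation.
#' @export
as_clone_set <- function(x) {
  need <- c("individual_id", "clone_id", "seq")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("clone set lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!nzchar(x$seq))) stop("clone set contains empty sequences")
  key <- paste(x$individual_id, x$clone_id)
  if (anyDuplicated(key)) {
    stop("duplicate (individual_id, clone_id): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  class(x) <- unique(c("clone_set", class(x)))
  x
}

#' Read a subpopulation label table
#'
#' @param path TSV with columns individual_id, subpop.
#' @return Named character vector mapping individual to subpopulation.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "subpop") %in% names(tab))) {
    stop("label table needs columns individual_id and subpop: ", path)
  }
  bad <- setdiff(unique(tab$subpop), c("north", "east", "admixed"))
  if (length(bad)) stop("unknown subpopulation label(s): ", paste(bad, collapse = ", "))
  stats::setNames(tab$subpop, tab$individual_id)
}

#' Write a subpopulation label table
#'
#' @param labels Named character vector (individual -> subpop).
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(individual_id = names(labels), subpop = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
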