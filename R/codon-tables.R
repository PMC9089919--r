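# Codon-level lookup tables shared by the classifier, the NG86 counter and
# the codon site models. Everything is derived once from the standard genetic
# code at install time.

.codon_env <- new.env(parent = emptyenv())

.build_codon_tables <- function() {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # outer() order above scrambles position order; rebuild explicitly
  all_codons <- apply(expand.grid(bases, bases, bases, stringsAsFactors = FALSE)[, 3:1],
                      1L, paste0, collapse = "")
  gc_map <- vapply(all_codons, function(cd) {
    as.character(Biostrings::GENETIC_CODE[[cd]])
  }, character(1))
  sense <- all_codons[gc_map != "*"]
  stops <- all_codons[gc_map == "*"]

  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)

  # single-nucleotide neighbour table over the 61 sense codons:
  # (from, to, position, transition?, synonymous?)
  nb_from <- integer(0); nb_to <- integer(0); nb_ts <- logical(0); nb_syn <- logical(0)
  idx <- seq_along(sense)
  names(idx) <- sense
  for (i in idx) {
    cd <- sense[i]
    sp <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (b in bases[bases != sp[pos]]) {
        alt <- sp
        alt[pos] <- b
        alt <- paste0(alt, collapse = "")
        if (gc_map[[alt]] == "*") next
        nb_from <- c(nb_from, i)
        nb_to <- c(nb_to, idx[[alt]])
        nb_ts <- c(nb_ts, purine[[sp[pos]]] == purine[[b]])
        nb_syn <- c(nb_syn, gc_map[[alt]] == gc_map[[cd]])
      }
    }
  }

  assign("bases", bases, envir = .codon_env)
  assign("all_codons", all_codons, envir = .codon_env)
  assign("gc_map", gc_map, envir = .codon_env)
  assign("sense_codons", sense, envir = .codon_env)
  assign("stop_codons", stops, envir = .codon_env)
  assign("sense_index", idx, envir = .codon_env)
  assign("purine", purine, envir = .codon_env)
  assign("neighbours", data.frame(from = nb_from, to = nb_to,
                                  transition = nb_ts, synonymous = nb_syn),
         envir = .codon_env)
  invisible(NULL)
}

.codon_tables <- function() {
  if (!exists("sense_codons", envir = .codon_env)) .build_codon_tables()
  .codon_env
}

#' Split an in-frame DNA string into codons
#'
#' @param seq DNA string (A/C/G/T), length a multiple of 3.
#' @return Character vector of codons.
#' @export
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a vector of codons with the standard genetic code
#'
#' @param codons Character vector of codons.
#' @return Character vector of single-letter amino acids ("*" for stop).
#' @export
translate_codons <- function(codons) {
  tb <- .codon_tables()
  aa <- tb$gc_map[codons]
  if (anyNA(aa)) stop("invalid codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  unname(aa)
}

is_stop_codon <- function(codons) {
  tb <- .codon_tables()
  codons %in% tb$stop_codons
}

#' Extract the complete in-frame codons of an amplicon
#'
#' The amplicon may start mid-codon; the first `frame_offset` nucleotides are
#' skipped and any incomplete trailing codon is dropped.
#'
#' @param seq DNA string.
#' @param frame_offset Number of leading nucleotides before the first
#'   complete codon (default 2).
#' @return Character vector of complete codons.
#' @export
inframe_codons <- function(seq, frame_offset = 2L) {
  n <- nchar(seq)
  if (n <= frame_offset) return(character(0))
  coding <- substr(seq, frame_offset + 1L, n)
  nc <- (nchar(coding) %/% 3L) * 3L
  if (nc == 0L) return(character(0))
  split_codons(substr(coding, 1L, nc))
}

random_sense_codons <- function(n) {
  tb <- .codon_tables()
  sample(tb$sense_codons, n, replace = TRUE)
}
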