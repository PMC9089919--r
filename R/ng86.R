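# Nei-Gojobori (1986) dN/dS with unweighted pathway averaging, exclusion of
# paths through stop codons, and Jukes-Cantor correction, partitioned into
# antigen-binding (ABS) and non-ABS codons. Standard errors come from a
# codon-column bootstrap.

#' Load an antigen-binding-site codon mask
#'
#' The default mask is the set of 18 codon positions (in 1..80 amplicon
#' coordinates) whose residues line the peptide-binding groove in the human
#' class II DR beta1 domain, the usual proxy when the study species has no
#' solved structure. A custom mask file lists one codon index per line
#' (`#` comments allowed).
#'
#' @param source Path to a mask file, or NULL for the packaged default.
#' @param n_codons Number of codons the mask indexes into (default 80).
#' @return An `abs_mask`: list(positions, n_codons).
#' @export
load_abs_mask <- function(source = NULL, n_codons = 80L) {
  if (is.null(source)) {
    source <- system.file("extdata", "abs_mask_default.txt", package = "drbdiv",
                          mustWork = TRUE)
  }
  lines <- readLines(source, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  pos <- suppressWarnings(as.integer(lines))
  if (anyNA(pos)) stop("non-integer entries in mask file: ", source)
  abs_mask(pos, n_codons)
}

#' Construct an ABS mask
#'
#' @param positions Integer codon indices (1-based).
#' @param n_codons Total codon count.
#' @return An `abs_mask`.
#' @export
abs_mask <- function(positions, n_codons = 80L) {
  positions <- sort(unique(as.integer(positions)))
  out_of_range <- positions[positions < 1L | positions > n_codons]
  if (length(out_of_range)) {
    stop("mask position(s) out of range 1..", n_codons, ": ",
         paste(out_of_range, collapse = ", "))
  }
  structure(list(positions = positions, n_codons = as.integer(n_codons)),
            class = "abs_mask")
}

#' Complement of an ABS mask
#'
#' @param mask An `abs_mask`.
#' @return An `abs_mask` over the non-ABS positions.
#' @export
mask_complement <- function(mask) {
  abs_mask(setdiff(seq_len(mask$n_codons), mask$positions), mask$n_codons)
}

#' Nei-Gojobori synonymous/nonsynonymous site counts for one codon
#'
#' At each codon position the three possible single-base changes are
#' classified; changes creating a stop codon are excluded from the
#' denominator of that position. The position contributes the synonymous
#' fraction to `s` and the rest to `n`, so `s + n = 3`.
#'
#' @param codon A sense codon (3-letter string).
#' @return Named numeric vector `c(s=, n=)`.
#' @export
ng_site_counts <- function(codon) {
  tb <- .codon_tables()
  if (is_stop_codon(codon)) stop("stop codon has no site counts: ", codon)
  if (!codon %in% tb$sense_codons) stop("not a valid codon: ", codon)
  sp <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (b in tb$bases[tb$bases != sp[pos]]) {
      alt <- sp; alt[pos] <- b
      alt <- paste0(alt, collapse = "")
      if (tb$gc_map[[alt]] == "*") next
      valid <- valid + 1L
      if (tb$gc_map[[alt]] == tb$gc_map[[codon]]) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

# average (synonymous, nonsynonymous) differences between two codons over all
# minimal substitution paths, skipping paths that pass through a stop codon
.codon_path_diffs <- function(c1, c2) {
  tb <- .codon_tables()
  if (c1 == c2) return(c(sd = 0, nd = 0))
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  diff_pos <- which(a != b)
  perms <- switch(as.character(length(diff_pos)),
    "1" = list(diff_pos),
    "2" = list(diff_pos, rev(diff_pos)),
    "3" = {
      p <- diff_pos
      list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)], p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])
    })
  tot <- c(sd = 0, nd = 0); nvalid <- 0L
  for (ord in perms) {
    cur <- a; sd_ <- 0; nd_ <- 0; valid <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- b[pos]
      cd_from <- paste0(cur, collapse = ""); cd_to <- paste0(nxt, collapse = "")
      if (tb$gc_map[[cd_to]] == "*") { valid <- FALSE; break }
      if (tb$gc_map[[cd_from]] == tb$gc_map[[cd_to]]) sd_ <- sd_ + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    if (valid) { tot <- tot + c(sd = sd_, nd = nd_); nvalid <- nvalid + 1L }
  }
  if (nvalid == 0L) {
    # all paths blocked by stops (only possible for extreme codon pairs);
    # fall back to averaging over all paths ignoring the stop constraint
    for (ord in perms) {
      cur <- a; sd_ <- 0; nd_ <- 0
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- b[pos]
        if (tb$gc_map[[paste0(cur, collapse = "")]] ==
            tb$gc_map[[paste0(nxt, collapse = "")]]) sd_ <- sd_ + 1 else nd_ <- nd_ + 1
        cur <- nxt
      }
      tot <- tot + c(sd = sd_, nd = nd_); nvalid <- nvalid + 1L
    }
  }
  tot / nvalid
}

# Jukes-Cantor correction; NA when saturated (p >= 3/4)
.jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & is.finite(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

#' Pairwise NG86 dN/dS between two in-frame codon sequences
#'
#' @param seqA,seqB Equal-length, in-frame (length a multiple of 3),
#'   stop-free DNA strings.
#' @param mask Optional `abs_mask` restricting the comparison to its
#'   positions.
#' @return A `pairwise_ng` list: Nd, Sd (path-averaged differences), N, S
#'   (site counts averaged over the two sequences), pN, pS, dN, dS
#'   (Jukes-Cantor corrected; NA with `dN_undefined`/`dS_undefined` flags
#'   when saturated), n_codons_compared.
#' @export
pairwise_dnds <- function(seqA, seqB, mask = NULL) {
  if (nchar(seqA) != nchar(seqB)) stop("length mismatch")
  codA <- split_codons(seqA); codB <- split_codons(seqB)
  if (any(is_stop_codon(codA)) || any(is_stop_codon(codB))) {
    stop("stop codon encountered")
  }
  idx <- seq_along(codA)
  if (!is.null(mask)) {
    if (mask$n_codons != length(codA)) stop("mask length does not match alignment")
    idx <- mask$positions
  }
  Nd <- 0; Sd <- 0; N <- 0; S <- 0
  for (i in idx) {
    sA <- ng_site_counts(codA[i]); sB <- ng_site_counts(codB[i])
    S <- S + (sA[["s"]] + sB[["s"]]) / 2
    N <- N + (sA[["n"]] + sB[["n"]]) / 2
    d <- .codon_path_diffs(codA[i], codB[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pN <- if (N > 0) Nd / N else NA_real_
  pS <- if (S > 0) Sd / S else NA_real_
  structure(list(Nd = Nd, Sd = Sd, N = N, S = S, pN = pN, pS = pS,
                 dN = .jc_correct(pN), dS = .jc_correct(pS),
                 dN_undefined = !is.na(pN) && pN >= 0.75,
                 dS_undefined = !is.na(pS) && pS >= 0.75,
                 n_codons_compared = length(idx)),
            class = "pairwise_ng")
}

# per-pair, per-codon contribution arrays used by partitioned_rates and its
# bootstrap: lists of matrices [pair, codon]
.ng_contributions <- function(aln) {
  seqs <- unname(aln)
  cods <- lapply(seqs, split_codons)
  nc <- length(cods[[1]])
  if (any(vapply(cods, length, integer(1)) != nc)) stop("alignment length mismatch")
  site_s <- do.call(rbind, lapply(cods, function(cs)
    vapply(cs, function(cd) ng_site_counts(cd)[["s"]], numeric(1))))
  pairs <- utils::combn(length(seqs), 2L)
  np <- ncol(pairs)
  sd_m <- matrix(0, np, nc); nd_m <- matrix(0, np, nc)
  s_m <- matrix(0, np, nc); n_m <- matrix(0, np, nc)
  for (p in seq_len(np)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    s_m[p, ] <- (site_s[i, ] + site_s[j, ]) / 2
    n_m[p, ] <- 3 - s_m[p, ]
    for (k in seq_len(nc)) {
      if (cods[[i]][k] != cods[[j]][k]) {
        d <- .codon_path_diffs(cods[[i]][k], cods[[j]][k])
        sd_m[p, k] <- d[["sd"]]; nd_m[p, k] <- d[["nd"]]
      }
    }
  }
  list(sd = sd_m, nd = nd_m, s = s_m, n = n_m, n_codons = nc)
}

# mean-of-pairs dN and dS over a set of codon columns
.ng_partition_rates <- function(contrib, cols) {
  Sd <- rowSums(contrib$sd[, cols, drop = FALSE])
  Nd <- rowSums(contrib$nd[, cols, drop = FALSE])
  S <- rowSums(contrib$s[, cols, drop = FALSE])
  N <- rowSums(contrib$n[, cols, drop = FALSE])
  dN <- .jc_correct(ifelse(N > 0, Nd / N, NA_real_))
  dS <- .jc_correct(ifelse(S > 0, Sd / S, NA_real_))
  c(dN = mean(dN, na.rm = TRUE), dS = mean(dS, na.rm = TRUE))
}

#' Partitioned NG86 rates with bootstrap standard errors
#'
#' Computes mean-of-pairs dN and dS over all unordered sequence pairs for
#' three partitions (overall, ABS, non-ABS), with standard errors from a
#' bootstrap that resamples codon columns within each partition, and
#' omega = dN/dS per partition.
#'
#' @param aln Named character vector of equal-length, in-frame, stop-free
#'   sequences (the functional-allele alignment).
#' @param mask An `abs_mask` over the alignment's codons.
#' @param bootstrap_reps Bootstrap replicates for the SEs (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return data.frame with rows overall/ABS/non-ABS: partition, n_codons,
#'   dN, dN_se, dS, dS_se, omega (NA when dS is 0 or undefined).
#' @export
partitioned_rates <- function(aln, mask, bootstrap_reps = 1000L, seed = NULL) {
  if (length(aln) < 2L) stop("need at least 2 sequences")
  if (!is.null(seed)) set.seed(seed)
  contrib <- .ng_contributions(aln)
  if (mask$n_codons != contrib$n_codons) stop("mask does not match alignment")
  parts <- list(overall = seq_len(contrib$n_codons),
                ABS = mask$positions,
                `non-ABS` = mask_complement(mask)$positions)
  rows <- lapply(names(parts), function(pn) {
    cols <- parts[[pn]]
    if (length(cols) == 0L) {
      return(data.frame(partition = pn, n_codons = 0L, dN = NA_real_,
                        dN_se = NA_real_, dS = NA_real_, dS_se = NA_real_,
                        omega = NA_real_, stringsAsFactors = FALSE))
    }
    est <- .ng_partition_rates(contrib, cols)
    boot <- matrix(NA_real_, bootstrap_reps, 2L)
    for (b in seq_len(bootstrap_reps)) {
      boot[b, ] <- .ng_partition_rates(
        contrib, sample(cols, length(cols), replace = TRUE))
    }
    omega <- if (!is.na(est[["dS"]]) && est[["dS"]] > 0) est[["dN"]] / est[["dS"]] else NA_real_
    data.frame(partition = pn, n_codons = length(cols),
               dN = est[["dN"]], dN_se = stats::sd(boot[, 1], na.rm = TRUE),
               dS = est[["dS"]], dS_se = stats::sd(boot[, 2], na.rm = TRUE),
               omega = omega, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
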