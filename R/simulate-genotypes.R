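# Multi-locus genotypes across two regional subpopulations. Frequencies are
# per haplotype: a haplotype is a single allele name, a "+"-joined linked
# allele pair (two linked loci inherited as a unit), or "(none)" for a
# null/absent haplotype (how individuals end up carrying fewer distinct
# alleles than loci).

NULL_HAPLOTYPE <- "(none)"

#' Simulate a two-subpopulation cohort of multi-locus genotypes
#'
#' Each individual draws two haplotypes per locus from its subpopulation's
#' haplotype frequency table. Presence of an allele (carrier state) is the
#' union over drawn haplotypes. Linked pairs (e.g. two alleles on linked
#' loci) are modelled as joint haplotypes, so they co-occur perfectly.
#'
#' @param pool An `allele_pool` supplying the sequences.
#' @param subpop_allele_freqs Named list (one element per subpopulation,
#'   names from north/east/admixed). Each element is a list of loci; each
#'   locus is a named numeric vector of haplotype frequencies summing to 1.
#'   Haplotype names are allele names from the pool, `A+B` for a linked
#'   pair, or `"(none)"`.
#' @param n_per_subpop Named integer vector of individuals per subpopulation.
#' @param linkage_pairs List of length-2 character vectors declaring linked
#'   allele pairs; linked alleles may appear only inside joint haplotypes.
#' @param seed Integer seed.
#' @return A `cohort_truth`: list with `individuals` (data.frame
#'   individual_id, subpop), `alleles` (named list of per-individual allele
#'   name vectors), `linkage_pairs`, and `pool`.
#' @export
simulate_genotypes <- function(pool, subpop_allele_freqs, n_per_subpop,
                               linkage_pairs = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(pool, "allele_pool"))
  known <- c(names(pool$functional), names(pool$pseudogene))
  bad_sp <- setdiff(names(subpop_allele_freqs), c("north", "east", "admixed"))
  if (length(bad_sp)) stop("unknown subpopulation(s): ", paste(bad_sp, collapse = ", "))
  if (is.null(names(n_per_subpop)) ||
      !all(names(n_per_subpop) %in% names(subpop_allele_freqs))) {
    stop("n_per_subpop must be named by subpopulations present in the frequency table")
  }

  for (sp in names(subpop_allele_freqs)) {
    for (loc in subpop_allele_freqs[[sp]]) {
      if (abs(sum(loc) - 1) > 1e-8) stop("haplotype frequencies must sum to 1 (", sp, ")")
      refs <- setdiff(unlist(strsplit(names(loc), "+", fixed = TRUE)), NULL_HAPLOTYPE)
      unknown <- setdiff(refs, known)
      if (length(unknown)) {
        stop("frequency table references unknown allele(s): ",
             paste(unknown, collapse = ", "))
      }
    }
  }
  for (lp in linkage_pairs) {
    if (length(lp) != 2L || !all(lp %in% known)) stop("invalid linkage pair")
  }

  individuals <- data.frame(individual_id = character(0), subpop = character(0),
                            stringsAsFactors = FALSE)
  alleles <- list()
  counter <- 0L
  for (sp in names(n_per_subpop)) {
    loci <- subpop_allele_freqs[[sp]]
    for (i in seq_len(n_per_subpop[[sp]])) {
      counter <- counter + 1L
      id <- sprintf("IND%02d", counter)
      for (try in seq_len(200L)) {
        drawn <- unlist(lapply(loci, function(fr) {
          sample(names(fr), 2L, replace = TRUE, prob = fr)
        }))
        got <- unique(setdiff(unlist(strsplit(drawn, "+", fixed = TRUE)), NULL_HAPLOTYPE))
        if (any(got %in% names(pool$functional))) break
      }
      if (!any(got %in% names(pool$functional))) {
        stop("could not draw an individual with at least one functional allele in ", sp)
      }
      individuals <- rbind(individuals, data.frame(
        individual_id = id, subpop = sp, stringsAsFactors = FALSE))
      alleles[[id]] <- sort(got)
    }
  }

  truth <- structure(list(individuals = individuals, alleles = alleles,
                          linkage_pairs = linkage_pairs, pool = pool),
                     class = "cohort_truth")
  .check_linkage(truth)
  truth
}

.check_linkage <- function(truth) {
  for (lp in truth$linkage_pairs) {
    for (al in truth$alleles) {
      if (xor(lp[1] %in% al, lp[2] %in% al)) {
        stop("linkage violated: ", lp[1], " without ", lp[2])
      }
    }
  }
  invisible(truth)
}

#' Write cohort ground truth as TSV
#'
#' @param truth A `cohort_truth`.
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- data.frame(
    individual_id = truth$individuals$individual_id,
    subpop = truth$individuals$subpop,
    alleles = vapply(truth$alleles[truth$individuals$individual_id],
                     paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default haplotype frequency tables emulating the study population
#'
#' Two regional subpopulations with divergent frequencies over three
#' functional haplotype slots and two pseudogene loci: one near-fixed common
#' allele (dominating the north), a linked allele pair at high frequency in
#' the east and low in the north, a handful of low-frequency alleles, one
#' pseudogene fixed in everyone and two rare ones.
#'
#' @param pool An `allele_pool` with >= 6 functional and >= 3 pseudogene alleles.
#' @return Named list of per-subpopulation locus frequency tables.
#' @export
default_cohort_freqs <- function(pool) {
  fn <- names(pool$functional)
  ps <- names(pool$pseudogene)
  stopifnot(length(fn) >= 6L, length(ps) >= 3L)
  rare_e <- fn[seq(7L, min(10L, length(fn)))]      # private to the east
  rare_n <- fn[seq(min(11L, length(fn)), length(fn))]  # private to the north
  pair <- paste0(fn[2], "+", fn[3])
  east <- list(
    locus1 = stats::setNames(
      c(0.45, 0.07, 0.02, 0.30, rep(0.16 / length(rare_e), length(rare_e))),
      c(fn[1], fn[4], fn[6], NULL_HAPLOTYPE, rare_e)),
    locus23 = stats::setNames(c(0.80, 0.20), c(pair, NULL_HAPLOTYPE)),
    ps_locus1 = stats::setNames(1, ps[1]),
    ps_locus2 = stats::setNames(
      c(0.04, 0.06, 0.90), c(ps[2], ps[3], NULL_HAPLOTYPE)))
  north <- list(
    locus1 = stats::setNames(
      c(0.78, 0.04, 0.02, 0.06, rep(0.10 / length(rare_n), length(rare_n))),
      c(fn[1], fn[4], fn[6], fn[5], rare_n)),
    locus23 = stats::setNames(c(0.16, 0.84), c(pair, NULL_HAPLOTYPE)),
    ps_locus1 = stats::setNames(1, ps[1]),
    ps_locus2 = stats::setNames(c(0.01, 0.01, 0.98), c(ps[2], ps[3], NULL_HAPLOTYPE)))
  list(east = east, north = north, admixed = north)
}

#' Simulate a full study-like cohort (pool, genotypes, clones)
#'
#' Convenience wrapper wiring the study conditions: 11 functional alleles and
#' 3 one-base-deletion pseudogenes over 80 codons, 19 eastern, 11 northern
#' and 2 admixed individuals, a perfectly linked allele pair, and on average
#' 26.9 clones per individual with PCR point errors and chimeras.
#'
#' @param seed Integer seed.
#' @param mean_clones Mean clones per individual (default 26.9).
#' @param error_rate Per-base substitution error probability (default 0.001).
#' @param chimera_rate Per-clone chimera probability (default 0.02).
#' @param target_divergence Allele pool divergence (default 0.2).
#' @return List with `pool`, `truth`, `clones`.
#' @export
simulate_wolverine_cohort <- function(seed = 1L, mean_clones = 26.9,
                                      error_rate = 0.001, chimera_rate = 0.02,
                                      target_divergence = 0.2) {
  pool <- simulate_allele_pool(11L, 3L, n_codons = 80L, frame_offset = 2L,
                               target_divergence = target_divergence,
                               kappa = 2, seed = seed)
  freqs <- default_cohort_freqs(pool)
  fn <- names(pool$functional)
  truth <- simulate_genotypes(pool, freqs,
                              n_per_subpop = c(east = 19L, north = 11L, admixed = 2L),
                              linkage_pairs = list(c(fn[2], fn[3])),
                              seed = seed + 1000L)
  clones <- simulate_clones(truth, mean_clones = mean_clones,
                            error_rate = error_rate, chimera_rate = chimera_rate,
                            seed = seed + 2000L)
  list(pool = pool, truth = truth, clones = clones)
}
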