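# Subpopulation comparisons on the genotype matrix. The Fisher exact test is
# computed by direct hypergeometric enumeration (the probability-mass rule
# for two-sided p, as in R's default) and the Welch t test from its closed
# form; both are cross-checked against stats in the test suite.

#' Merge admixed individuals into a subpopulation
#'
#' @param gm A `genotype_matrix`.
#' @param into Target subpopulation (default "north", matching the study's
#'   geographic assignment of its two admixed individuals).
#' @return The genotype matrix with `admixed` labels replaced.
#' @export
merge_admixed <- function(gm, into = "north") {
  if (!into %in% c("north", "east")) stop("merge target must be north or east")
  gm$subpop[gm$subpop == "admixed"] <- into
  gm
}

#' Per-subpopulation carrier counts
#'
#' Counts individuals carrying a set of alleles under a mode: `all` (carries
#' every allele in the set), `any` (at least one), or
#' `exactly_one_functional` (the individual's functional-allele count is 1;
#' `allele_set` is ignored).
#'
#' @param gm A `genotype_matrix`.
#' @param allele_set Character vector of allele names.
#' @param mode Counting mode.
#' @param merge_admixed_into Subpopulation receiving admixed individuals
#'   before counting (default "north"); NULL keeps admixed separate.
#' @return data.frame(subpop, carriers, n).
#' @export
carrier_counts <- function(gm, allele_set = character(0),
                           mode = c("all", "any", "exactly_one_functional"),
                           merge_admixed_into = "north") {
  mode <- match.arg(mode)
  if (!is.null(merge_admixed_into)) gm <- merge_admixed(gm, merge_admixed_into)
  unknown <- setdiff(allele_set, colnames(gm$presence))
  if (length(unknown)) stop("unknown allele name(s): ", paste(unknown, collapse = ", "))
  carrier <- switch(mode,
    all = if (length(allele_set) == 0L) rep(TRUE, nrow(gm$presence))
          else rowSums(gm$presence[, allele_set, drop = FALSE]) == length(allele_set),
    any = if (length(allele_set) == 0L) rep(FALSE, nrow(gm$presence))
          else rowSums(gm$presence[, allele_set, drop = FALSE]) > 0L,
    exactly_one_functional =
      rowSums(gm$presence[, gm$status == "functional", drop = FALSE]) == 1L)
  sp <- unname(gm$subpop)
  out <- do.call(rbind, lapply(sort(unique(sp)), function(s) {
    data.frame(subpop = s, carriers = sum(carrier[sp == s]), n = sum(sp == s),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Enumerates all tables with the observed margins; the two-sided p-value is
#' the sum of hypergeometric probabilities of tables whose probability does
#' not exceed that of the observed table (probability-mass rule).
#'
#' @param tab 2x2 matrix of non-negative counts
#'   (rows = subpopulations, columns = trait present/absent).
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  n <- sum(tab)
  if (n == 0L) stop("table total is zero")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
  a_range <- max(0L, c1 - (n - r1)):min(r1, c1)
  logp <- lchoose(r1, a_range) + lchoose(n - r1, c1 - a_range) - lchoose(n, c1)
  p_obs <- logp[match(tab[1, 1], a_range)]
  # relative tolerance mirrors fisher.test's handling of floating ties
  sum(exp(logp[logp <= p_obs + 1e-7])) |> min(1)
}

#' Welch two-sample t test (unequal variances)
#'
#' @param groupA,groupB Numeric vectors, each with >= 2 values and positive
#'   variance in at least one group.
#' @return List with `t`, `df` (Welch-Satterthwaite) and two-sided `p`.
#' @export
welch_t_test <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L) stop("each group needs >= 2 values")
  vA <- stats::var(groupA); vB <- stats::var(groupB)
  nA <- length(groupA); nB <- length(groupB)
  if (vA == 0 && vB == 0) {
    if (mean(groupA) == mean(groupB)) return(list(t = 0, df = nA + nB - 2, p = 1))
    stop("degenerate: both groups have zero variance and different means")
  }
  se2 <- vA / nA + vB / nB
  t <- (mean(groupA) - mean(groupB)) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Diversity summary of a genotype matrix
#'
#' Per-subpopulation mean counts of functional alleles and pseudogenes per
#' individual, the maximum number of functional alleles in one individual,
#' the implied lower bound on the number of loci (`ceiling(max / 2)` per
#' haploid genome), and per-allele carrier frequencies by subpopulation.
#'
#' @param gm A `genotype_matrix`.
#' @param merge_admixed_into Subpopulation receiving admixed individuals
#'   (default "north"); NULL keeps them separate.
#' @return List: `mean_functional`, `mean_pseudogene` (named by subpop),
#'   `max_alleles`, `locus_lower_bound`, `carrier_freq` (allele x subpop).
#' @export
summarize_diversity <- function(gm, merge_admixed_into = "north") {
  if (!is.null(merge_admixed_into)) gm <- merge_admixed(gm, merge_admixed_into)
  fn <- gm$status == "functional"
  counts_f <- rowSums(gm$presence[, fn, drop = FALSE])
  counts_p <- rowSums(gm$presence[, !fn, drop = FALSE])
  sp <- unname(gm$subpop)
  sps <- sort(unique(sp))
  mean_f <- vapply(sps, function(s) mean(counts_f[sp == s]), numeric(1))
  mean_p <- vapply(sps, function(s) mean(counts_p[sp == s]), numeric(1))
  freq <- vapply(sps, function(s) colMeans(gm$presence[sp == s, , drop = FALSE]),
                 numeric(ncol(gm$presence)))
  max_alleles <- max(counts_f)
  list(mean_functional = mean_f, mean_pseudogene = mean_p,
       max_alleles = as.integer(max_alleles),
       locus_lower_bound = as.integer(ceiling(max_alleles / 2)),
       carrier_freq = freq)
}
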