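# Minimal codon-alignment simulator used for parameter-recovery testing of
# the site models: sites evolve independently under a GY94-style matrix with
# a per-site omega, on a fixed tree whose branch lengths are expected
# substitutions per codon under the mixture-averaged generator (the same
# normalization the fitting engine uses).

#' Simulate a codon alignment with per-site omega classes
#'
#' @param tree An `ape::phylo` with branch lengths (expected substitutions
#'   per codon under the weight-averaged generator).
#' @param n_codons Number of codon sites.
#' @param kappa Transition/transversion ratio.
#' @param omegas Numeric vector of class omega values.
#' @param weights Class probabilities (same length as `omegas`, sum 1);
#'   ignored when `site_classes` is given.
#' @param site_classes Optional integer vector (length `n_codons`) fixing
#'   each site's class.
#' @param pi Codon frequencies over the 61 sense codons (default equal).
#' @param seed Integer seed.
#' @return List with `aln` (named character vector of in-frame sequences,
#'   tips of the tree) and `site_classes` (the realized class of each site).
#' @export
simulate_codon_alignment <- function(tree, n_codons, kappa = 2, omegas = 1,
                                     weights = NULL, site_classes = NULL,
                                     pi = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tb <- .codon_tables()
  nstate <- length(tb$sense_codons)
  if (is.null(pi)) pi <- rep(1 / nstate, nstate)
  if (is.null(site_classes)) {
    if (is.null(weights)) weights <- rep(1 / length(omegas), length(omegas))
    site_classes <- sample(seq_along(omegas), n_codons, replace = TRUE,
                           prob = weights)
  } else {
    stopifnot(length(site_classes) == n_codons)
    weights <- as.vector(table(factor(site_classes, levels = seq_along(omegas))))
    weights <- weights / sum(weights)
  }
  Qs <- lapply(omegas, .codon_Q, kappa = kappa, pi = pi)
  flux <- sum(weights * vapply(Qs, `[[`, numeric(1), "flux"))
  eigs <- lapply(Qs, .eigen_Q, pi = pi)

  post <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(post$edge)))  # preorder over edges
  ntip <- length(post$tip.label)
  nn <- ntip + post$Nnode
  states <- matrix(NA_integer_, nn, n_codons)
  root <- ntip + 1L
  states[root, ] <- sample.int(nstate, n_codons, replace = TRUE, prob = pi)
  for (e in pre) {
    par <- post$edge[e, 1]; ch <- post$edge[e, 2]
    t <- post$edge.length[e] / flux
    for (k in seq_along(omegas)) {
      sites <- which(site_classes == k)
      if (!length(sites)) next
      P <- .prob_matrix(eigs[[k]], t)
      from <- states[par, sites]
      states[ch, sites] <- vapply(from, function(s) {
        sample.int(nstate, 1L, prob = P[s, ])
      }, integer(1))
    }
  }
  aln <- vapply(seq_len(ntip), function(i) {
    paste0(tb$sense_codons[states[i, ]], collapse = "")
  }, character(1))
  names(aln) <- post$tip.label
  list(aln = aln, site_classes = site_classes)
}

#' A symmetric test tree for simulation studies
#'
#' Balanced when `n_tips` is a power of two, otherwise a ladder; uniform
#' branch lengths scaled so the maximum root-to-tip path equals
#' `total_depth`.
#'
#' @param n_tips Number of tips (default 8).
#' @param total_depth Root-to-tip path length in expected substitutions per
#'   codon (default 0.5).
#' @return An unrooted `ape::phylo`.
#' @export
balanced_sim_tree <- function(n_tips = 8L, total_depth = 0.5) {
  type <- if (log2(n_tips) %% 1 == 0) "balanced" else "left"
  tr <- ape::stree(n_tips, type = type)
  tr$edge.length <- rep(1, nrow(tr$edge))
  depth <- max(ape::node.depth.edgelength(tr)[seq_len(n_tips)])
  tr$edge.length <- rep(total_depth / depth, nrow(tr$edge))
  ape::unroot(tr)
}
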