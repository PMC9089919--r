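# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the codon likelihood oracle builds the rate
# matrix by explicit loops and exponentiates it with Matrix::expm; the
# Fisher oracle enumerates tables with plain factorials.

codon_tables_for_tests <- function() drbdiv:::.codon_tables()

# dense matrix-exponential likelihood for a single-omega codon model
oracle_codon_lnL <- function(aln, tree, kappa, omega, pi_vec, scale = 1) {
  tb <- codon_tables_for_tests()
  sense <- tb$sense_codons
  n <- length(sense)
  pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- strsplit(sense[i], "")[[1]]
    b <- strsplit(sense[j], "")[[1]]
    dd <- which(a != b)
    if (length(dd) != 1L) next
    r <- pi_vec[j]
    if (pur[[a[dd]]] == pur[[b[dd]]]) r <- r * kappa
    if (tb$gc_map[[sense[i]]] != tb$gc_map[[sense[j]]]) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  flux <- -sum(pi_vec * diag(Q))
  post <- ape::reorder.phylo(tree, "postorder")
  Ps <- lapply(post$edge.length * scale / flux,
               function(t) as.matrix(Matrix::expm(Q * t)))
  cods <- lapply(unname(aln), split_codons)
  idx <- stats::setNames(seq_len(n), sense)
  ntip <- length(post$tip.label)
  ord <- match(post$tip.label, names(aln))
  total <- 0
  for (s in seq_along(cods[[1]])) {
    L <- vector("list", ntip + post$Nnode)
    for (i in seq_len(ntip)) {
      v <- rep(0, n); v[idx[[cods[[ord[i]]][s]]]] <- 1; L[[i]] <- v
    }
    for (e in seq_len(nrow(post$edge))) {
      par <- post$edge[e, 1]; ch <- post$edge[e, 2]
      m <- Ps[[e]] %*% L[[ch]]
      L[[par]] <- if (is.null(L[[par]])) m else L[[par]] * m
    }
    total <- total + log(sum(pi_vec * L[[ntip + 1]]))
  }
  total
}

# the package's likelihood at fixed parameters, via its internal engine
package_codon_lnL <- function(aln, tree, kappa, omega, pi_vec, scale = 1) {
  fd <- drbdiv:::.codon_fit_data(aln, tree, pi_vec)
  lf <- drbdiv:::.class_logliks(fd, kappa, omega, 1, scale)
  drbdiv:::.mixture_loglik(fd, lf, 1)
}

# brute-force two-sided Fisher p by enumerating all tables with the margins,
# with probabilities from plain factorial products
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(a_range, function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
          lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(cc) -
          lfactorial(d))
  }, numeric(1))
  p_obs <- prob[match(tab[1, 1], a_range)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# monophyly by rooting at an outgroup tip and using ape's clade test
oracle_monophyletic <- function(tree, tips_of_species) {
  other <- setdiff(tree$tip.label, tips_of_species)
  rooted <- ape::root(tree, outgroup = other[1], resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips_of_species)
}

# small deterministic random tree with positive branch lengths
random_test_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = FALSE)
  tr$edge.length <- abs(tr$edge.length) + 0.05
  tr
}
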