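# Codon substitution likelihood engine: GY94-style rate matrix over the 61
# sense codons (transition/transversion ratio kappa, nonsynonymous factor
# omega, target-codon frequencies pi), matrix exponentials via the
# symmetric eigendecomposition of the reversible generator, and Felsenstein
# pruning vectorized over site patterns with per-pattern scaling.

#' Codon frequency estimates for a codon alignment
#'
#' @param aln Named character vector of in-frame sequences.
#' @param type "f3x4" (position-specific nucleotide frequencies, the common
#'   default) or "equal" (1/61 each).
#' @return Numeric vector of length 61 (sense codons), summing to 1.
#' @export
codon_frequencies <- function(aln, type = c("f3x4", "equal")) {
  type <- match.arg(type)
  tb <- .codon_tables()
  sense <- tb$sense_codons
  if (type == "equal") {
    return(stats::setNames(rep(1 / length(sense), length(sense)), sense))
  }
  cods <- unlist(lapply(unname(aln), split_codons))
  mat <- do.call(rbind, strsplit(cods, ""))
  f <- sapply(1:3, function(p) {
    tab <- table(factor(mat[, p], levels = tb$bases))
    as.numeric(tab) / sum(tab)
  })
  rownames(f) <- tb$bases
  pi <- vapply(sense, function(cd) {
    sp <- strsplit(cd, "")[[1]]
    f[sp[1], 1] * f[sp[2], 2] * f[sp[3], 3]
  }, numeric(1))
  pi <- pmax(pi, 1e-8)
  pi / sum(pi)
}

# unscaled GY94 rate matrix and its flux rate under pi
.codon_Q <- function(kappa, omega, pi) {
  tb <- .codon_tables()
  nb <- tb$neighbours
  n <- length(tb$sense_codons)
  Q <- matrix(0, n, n)
  rate <- pi[nb$to] * ifelse(nb$transition, kappa, 1) * ifelse(nb$synonymous, 1, omega)
  Q[cbind(nb$from, nb$to)] <- rate
  diag(Q) <- -rowSums(Q)
  list(Q = Q, flux = -sum(pi * diag(Q)))
}

# eigendecomposition of the reversible generator for fast P(t)
.eigen_Q <- function(Qobj, pi) {
  sq <- sqrt(pi)
  B <- Qobj$Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(V = e$vectors / sq, Vi = t(e$vectors) * rep(sq, each = nrow(B)),
       values = e$values)
}

.prob_matrix <- function(eig, t) {
  if (t <= 1e-12) return(diag(length(eig$values)))
  P <- eig$V %*% (exp(eig$values * t) * eig$Vi)
  P[P < 0] <- 0
  P
}

# precompute everything that does not change during optimization
.codon_fit_data <- function(aln, tree, pi) {
  tb <- .codon_tables()
  idx <- tb$sense_index
  cods <- lapply(unname(aln), split_codons)
  nsite <- length(cods[[1]])
  if (any(vapply(cods, length, integer(1)) != nsite)) stop("alignment length mismatch")
  codmat <- do.call(rbind, cods)  # ntaxa x nsite codon strings
  if (any(is_stop_codon(codmat))) stop("stop codon in alignment")
  statemat <- matrix(idx[codmat], nrow(codmat), nsite)

  pat_key <- apply(statemat, 2L, paste, collapse = ",")
  upat <- unique(pat_key)
  pat_of_site <- match(pat_key, upat)
  weights <- as.vector(table(factor(pat_of_site, levels = seq_along(upat))))
  first_site <- match(seq_along(upat), pat_of_site)
  pat_states <- statemat[, first_site, drop = FALSE]

  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  if (!setequal(tree$tip.label, names(aln))) {
    stop("tree tips do not match sequence names")
  }
  post <- ape::reorder.phylo(tree, "postorder")
  tip_order <- match(post$tip.label, names(aln))

  nstate <- length(tb$sense_codons)
  ntip <- length(post$tip.label)
  tipmats <- lapply(seq_len(ntip), function(i) {
    M <- matrix(0, nstate, length(upat))
    M[cbind(pat_states[tip_order[i], ], seq_along(upat))] <- 1
    M
  })
  list(post = post, tipmats = tipmats, weights = weights,
       pat_of_site = pat_of_site, npat = length(upat), nsite = nsite,
       ntip = ntip, pi = pi, nstate = nstate,
       pat_variable = apply(pat_states, 2L, function(x) length(unique(x)) > 1L))
}

# per-pattern log-likelihood for a single omega class, given edge P matrices
.prune_class <- function(fd, Plist) {
  post <- fd$post
  nn <- fd$ntip + post$Nnode
  partial <- vector("list", nn)
  logsc <- matrix(0, nn, fd$npat)
  for (i in seq_len(fd$ntip)) partial[[i]] <- fd$tipmats[[i]]
  edges <- post$edge
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; ch <- edges[e, 2]
    M <- Plist[[e]] %*% partial[[ch]]
    if (is.null(partial[[par]])) {
      partial[[par]] <- M
      logsc[par, ] <- logsc[ch, ]
    } else {
      partial[[par]] <- partial[[par]] * M
      logsc[par, ] <- logsc[par, ] + logsc[ch, ]
      mx <- apply(partial[[par]], 2L, max)
      mx[mx <= 0] <- 1
      partial[[par]] <- sweep(partial[[par]], 2L, mx, "/")
      logsc[par, ] <- logsc[par, ] + log(mx)
    }
  }
  root <- fd$ntip + 1L
  log(colSums(partial[[root]] * fd$pi)) + logsc[root, ]
}

# class-by-pattern log-likelihood matrix for a mixture of omega classes.
# Branch lengths are edge.length * scale, in expected substitutions per codon
# under the weight-averaged generator (common normalization across classes).
.class_logliks <- function(fd, kappa, omegas, weights, scale) {
  Qs <- lapply(omegas, .codon_Q, kappa = kappa, pi = fd$pi)
  flux <- sum(weights * vapply(Qs, `[[`, numeric(1), "flux"))
  if (flux <= 0) return(NULL)
  el <- fd$post$edge.length * scale / flux
  out <- matrix(NA_real_, length(omegas), fd$npat)
  for (k in seq_along(omegas)) {
    if (weights[k] <= 0) next
    eig <- .eigen_Q(Qs[[k]], fd$pi)
    Plist <- lapply(el, .prob_matrix, eig = eig)
    out[k, ] <- .prune_class(fd, Plist)
  }
  out
}

# total log-likelihood of the mixture from the class-by-pattern matrix
.mixture_loglik <- function(fd, log_fk, weights) {
  active <- which(weights > 0)
  lw <- log(weights[active])
  lf <- log_fk[active, , drop = FALSE] + lw
  m <- apply(lf, 2L, max)
  site_ll <- m + log(colSums(exp(sweep(lf, 2L, m, "-"))))
  sum(fd$weights * site_ll)
}

#' Mean category values of a discretized beta distribution
#'
#' K equal-probability categories of Beta(p, q), each represented by its
#' conditional mean.
#'
#' @param p,q Beta shape parameters (> 0).
#' @param K Number of categories (default 10).
#' @return Numeric vector of K category means in (0, 1).
#' @export
beta_category_means <- function(p, q, K = 10L) {
  # extreme shapes can push qbeta/pbeta past full precision; the guard below
  # replaces any degenerate category mean, so the warnings carry no signal
  b <- suppressWarnings(stats::qbeta(seq(0, 1, length.out = K + 1L), p, q))
  cdf1 <- suppressWarnings(stats::pbeta(b, p + 1, q))
  means <- (p / (p + q)) * diff(cdf1) * K
  # guard numerically degenerate categories (extreme p, q)
  mid <- (b[-1] + b[-(K + 1L)]) / 2
  bad <- !is.finite(means) | means <= 0 | means >= 1
  means[bad] <- pmin(pmax(mid[bad], 1e-8), 1 - 1e-8)
  means
}
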