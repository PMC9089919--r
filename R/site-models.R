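# Codon site models M0, M1a, M2a, M7 and M8 on a fixed topology:
# maximum-likelihood fitting by multi-start bounded quasi-Newton
# optimization, likelihood ratio tests between nested pairs, and
# empirical-Bayes identification of positively selected sites (naive
# empirical Bayes at the MLEs, or Bayes empirical Bayes over a grid on the
# class parameters).

.MODEL_IDS <- c("M0", "M1a", "M2a", "M7", "M8")

# parameter packing: each model maps an unconstrained vector to
# (kappa, scale, omegas, weights); bounds are on the transformed scale
.model_pack <- function(model, ncat = 10L) {
  lg <- function(x) log(x)
  switch(model,
    M0 = list(
      start = c(lkappa = lg(2), lscale = lg(1), lomega = lg(0.3)),
      lower = c(lg(0.1), lg(1e-3), lg(1e-4)),
      upper = c(lg(20), lg(100), lg(50)),
      unpack = function(p) {
        list(kappa = exp(p[1]), scale = exp(p[2]),
             omegas = exp(p[3]), weights = 1)
      },
      npar = 3L),
    M1a = list(
      start = c(lkappa = lg(2), lscale = lg(1), qp0 = 0.8, qw0 = -2),
      lower = c(lg(0.1), lg(1e-3), -15, -9.2),
      upper = c(lg(20), lg(100), 15, 9.2),
      unpack = function(p) {
        p0 <- stats::plogis(p[3])
        list(kappa = exp(p[1]), scale = exp(p[2]),
             omegas = c(stats::plogis(p[4]), 1), weights = c(p0, 1 - p0))
      },
      npar = 4L),
    M2a = list(
      start = c(lkappa = lg(2), lscale = lg(1), s0 = 1.5, s1 = 0.8,
                qw0 = -2, lw2m1 = lg(2)),
      lower = c(lg(0.1), lg(1e-3), -15, -15, -9.2, lg(1e-4)),
      upper = c(lg(20), lg(100), 15, 15, 9.2, lg(49)),
      unpack = function(p) {
        ew <- exp(c(p[3], p[4], 0))
        w <- ew / sum(ew)
        list(kappa = exp(p[1]), scale = exp(p[2]),
             omegas = c(stats::plogis(p[5]), 1, 1 + exp(p[6])),
             weights = w)
      },
      npar = 6L),
    M7 = list(
      start = c(lkappa = lg(2), lscale = lg(1), lp = lg(0.5), lq = lg(0.5)),
      lower = c(lg(0.1), lg(1e-3), lg(0.005), lg(0.005)),
      upper = c(lg(20), lg(100), lg(99), lg(99)),
      unpack = function(p) {
        means <- beta_category_means(exp(p[3]), exp(p[4]), ncat)
        list(kappa = exp(p[1]), scale = exp(p[2]),
             omegas = means, weights = rep(1 / ncat, ncat))
      },
      npar = 4L),
    M8 = list(
      start = c(lkappa = lg(2), lscale = lg(1), qp0 = 1.5, lp = lg(0.5),
                lq = lg(0.5), lwsm1 = lg(2)),
      lower = c(lg(0.1), lg(1e-3), -15, lg(0.005), lg(0.005), lg(1e-4)),
      upper = c(lg(20), lg(100), 15, lg(99), lg(99), lg(49)),
      unpack = function(p) {
        p0 <- stats::plogis(p[3])
        means <- beta_category_means(exp(p[4]), exp(p[5]), ncat)
        list(kappa = exp(p[1]), scale = exp(p[2]),
             omegas = c(means, 1 + exp(p[6])),
             weights = c(rep(p0 / ncat, ncat), 1 - p0))
      },
      npar = 6L),
    stop("unknown model: ", model))
}

#' Fit a codon site model by maximum likelihood
#'
#' Fits kappa, the omega-class parameters and a global branch-length scale
#' (optionally every branch length) on a fixed topology, by L-BFGS-B from
#' multiple seeded starting points. The likelihood is the Felsenstein
#' pruning likelihood over the 61 sense codons with the model's omega-class
#' mixture applied per site.
#'
#' @param aln Named character vector of equal-length in-frame stop-free
#'   codon sequences.
#' @param tree An `ape::phylo` with branch lengths and tips matching
#'   `names(aln)`; NULL builds a neighbor-joining tree from K80 distances.
#' @param model One of "M0", "M1a", "M2a", "M7", "M8".
#' @param freq Codon frequency model: "f3x4" (default) or "equal".
#' @param restarts Number of optimization starts (default 5).
#' @param seed Integer seed for the start-point jitter.
#' @param branches "scale" (default) optimizes a single tree-scale factor on
#'   the input branch lengths; "all" additionally optimizes every branch
#'   length.
#' @param ncat Number of beta categories for M7/M8 (default 10).
#' @return A `site_model_fit`: model, lnL, parameters (natural scale),
#'   `classes` (data.frame omega, weight), per-site posterior matrix
#'   (sites x classes), tree, pi, convergence report.
#' @export
fit_site_model <- function(aln, tree = NULL, model = "M1a",
                           freq = c("f3x4", "equal"), restarts = 5L,
                           seed = NULL, branches = c("scale", "all"),
                           ncat = 10L) {
  model <- match.arg(model, .MODEL_IDS)
  freq <- match.arg(freq)
  branches <- match.arg(branches)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) tree <- nj_tree_from_sequences(aln)
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  pi <- codon_frequencies(aln, freq)
  fd <- .codon_fit_data(aln, tree, pi)
  pack <- .model_pack(model, ncat)

  nb <- if (branches == "all") length(fd$post$edge.length) else 0L
  base_el <- fd$post$edge.length
  objective <- function(p) {
    mp <- pack$unpack(p[seq_len(pack$npar)])
    if (nb > 0L) {
      fd$post$edge.length <- exp(p[pack$npar + seq_len(nb)])
    }
    lf <- .class_logliks(fd, mp$kappa, mp$omegas, mp$weights, mp$scale)
    if (is.null(lf) || any(!is.finite(lf[mp$weights > 0, ]))) return(1e10)
    -.mixture_loglik(fd, lf, mp$weights)
  }

  lower <- c(pack$lower, rep(log(1e-6), nb))
  upper <- c(pack$upper, rep(log(20), nb))
  best <- NULL
  n_starts <- max(1L, as.integer(restarts))
  conv <- data.frame(start = integer(0), value = numeric(0), converged = logical(0))
  for (s in seq_len(n_starts)) {
    p0 <- c(pack$start, if (nb > 0L) log(base_el))
    if (s > 1L) {
      p0[seq_len(pack$npar)] <- p0[seq_len(pack$npar)] +
        stats::runif(pack$npar, -1, 1)
      p0 <- pmin(pmax(p0, lower + 1e-6), upper - 1e-6)
    }
    res <- tryCatch(
      stats::optim(p0, objective, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500L, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res)) next
    conv <- rbind(conv, data.frame(start = s, value = -res$value,
                                   converged = res$convergence == 0L))
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("optimization failed from every start")

  mp <- pack$unpack(best$par[seq_len(pack$npar)])
  if (nb > 0L) fd$post$edge.length <- exp(best$par[pack$npar + seq_len(nb)])
  log_fk <- .class_logliks(fd, mp$kappa, mp$omegas, mp$weights, mp$scale)
  lnL <- .mixture_loglik(fd, log_fk, mp$weights)

  # per-site class posteriors at the MLEs (rows sum to 1)
  lw <- log(ifelse(mp$weights > 0, mp$weights, 1))
  lp <- log_fk + lw
  lp[mp$weights <= 0, ] <- -Inf
  m <- apply(lp, 2L, max)
  post_pat <- t(exp(sweep(lp, 2L, m, "-")))
  post_pat <- post_pat / rowSums(post_pat)
  posteriors <- post_pat[fd$pat_of_site, , drop = FALSE]
  rownames(posteriors) <- seq_len(fd$nsite)

  params <- switch(model,
    M0 = list(kappa = mp$kappa, scale = mp$scale, omega = mp$omegas[1]),
    M1a = list(kappa = mp$kappa, scale = mp$scale, p0 = mp$weights[1],
               p1 = mp$weights[2], omega0 = mp$omegas[1], omega1 = 1),
    M2a = list(kappa = mp$kappa, scale = mp$scale, p0 = mp$weights[1],
               p1 = mp$weights[2], p2 = mp$weights[3],
               omega0 = mp$omegas[1], omega1 = 1, omega2 = mp$omegas[3]),
    M7 = list(kappa = mp$kappa, scale = mp$scale,
              p = exp(best$par[3]), q = exp(best$par[4])),
    M8 = list(kappa = mp$kappa, scale = mp$scale,
              p0 = stats::plogis(best$par[3]), p1 = 1 - stats::plogis(best$par[3]),
              p = exp(best$par[4]), q = exp(best$par[5]),
              omega_s = mp$omegas[length(mp$omegas)]))

  structure(list(model = model, lnL = lnL, params = params,
                 classes = data.frame(omega = mp$omegas, weight = mp$weights),
                 posteriors = posteriors, tree = fd$post, pi = pi,
                 fit_data = fd, mle_transformed = best$par[seq_len(pack$npar)],
                 ncat = ncat, convergence = conv),
            class = "site_model_fit")
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat("site_model_fit:", x$model, " lnL =", formatC(x$lnL, digits = 4, format = "f"), "\n")
  cat("classes:\n")
  print(round(x$classes, 4))
  invisible(x)
}

.NESTED_PAIRS <- list(c("M1a", "M2a"), c("M7", "M8"), c("M0", "M2a"))

#' Likelihood ratio test between two nested site-model fits
#'
#' @param null_fit,alt_fit `site_model_fit` objects; the null must be nested
#'   in the alternative (M1a in M2a, M7 in M8, M0 in M2a).
#' @param df Degrees of freedom (default 2, the standard value for both
#'   M1a-M2a and M7-M8).
#' @return List with `delta` (2 * (lnL_alt - lnL_null), clamped at 0),
#'   `df`, and `p` (chi-square upper tail).
#' @export
likelihood_ratio_test <- function(null_fit, alt_fit, df = 2L) {
  pair <- c(null_fit$model, alt_fit$model)
  ok <- any(vapply(.NESTED_PAIRS, function(np) identical(np, pair), logical(1)))
  if (!ok) stop(pair[1], " is not nested in ", pair[2])
  delta <- max(0, 2 * (alt_fit$lnL - null_fit$lnL))
  list(delta = delta, df = df, p = stats::pchisq(delta, df, lower.tail = FALSE))
}

#' Identify positively selected sites from a site-model fit
#'
#' Reports sites whose posterior probability of belonging to the
#' positive-selection class (omega > 1) exceeds the threshold. `NEB`
#' evaluates the posterior at the MLEs; `BEB` integrates over a 10-point
#' grid per class parameter with a uniform prior, holding kappa and branch
#' lengths at their MLEs.
#'
#' Sites with no variation across sequences carry no substitution evidence;
#' they are never flagged (an invariant alignment yields an empty list even
#' when the flat likelihood leaves the class weights unidentified).
#'
#' @param fit A `site_model_fit` for M2a or M8.
#' @param threshold Posterior probability threshold (default 0.95).
#' @param method "NEB" (default) or "BEB".
#' @return data.frame(site, posterior) for sites above the threshold, with
#'   attribute `all_posteriors` (per-site positive-class posterior).
#' @export
identify_selected_sites <- function(fit, threshold = 0.95,
                                    method = c("NEB", "BEB")) {
  method <- match.arg(method)
  if (!fit$model %in% c("M2a", "M8")) {
    stop("model ", fit$model, " has no positive-selection class")
  }
  pos_class <- nrow(fit$classes)  # last class is the omega >= 1 class
  if (method == "NEB") {
    pp <- fit$posteriors[, pos_class]
  } else {
    pp <- .beb_positive_posterior(fit)
  }
  variable <- fit$fit_data$pat_variable[fit$fit_data$pat_of_site]
  sel <- which(pp > threshold & variable)
  out <- data.frame(site = sel, posterior = pp[sel])
  attr(out, "all_posteriors") <- pp
  out
}

# Bayes empirical Bayes over the class-parameter grid (10 points per
# dimension, uniform prior), kappa/scale fixed at their MLEs.
.beb_positive_posterior <- function(fit, d = 10L) {
  fd <- fit$fit_data
  kappa <- fit$params$kappa
  scale <- fit$params$scale
  mid <- (seq_len(d) - 0.5) / d

  if (fit$model == "M2a") {
    w0_grid <- mid
    w2_grid <- 1 + mid * 10
    omegas <- c(w0_grid, 1, w2_grid)
    # site log-likelihood for every omega value, at a fixed flux normalization
    log_f <- .grid_site_logliks(fd, kappa, omegas, scale,
                                ref_omegas = fit$classes$omega,
                                ref_weights = fit$classes$weight)
    pcombo <- expand.grid(i0 = seq_len(d), i1 = seq_len(d))
    pcombo <- pcombo[mid[pcombo$i0] + mid[pcombo$i1] <= 1, ]
    grid <- expand.grid(pc = seq_len(nrow(pcombo)), iw0 = seq_len(d),
                        iw2 = seq_len(d))
    npat <- fd$npat
    log_post_num <- rep(-Inf, npat)   # accumulating over grid, per pattern
    log_marg <- -Inf
    contrib_pos <- rep(0, npat)
    # first pass: log f(X|g) for every grid point
    ngrid <- nrow(grid)
    logfXg <- numeric(ngrid)
    pos_site <- matrix(0, ngrid, npat)
    for (g in seq_len(ngrid)) {
      p0 <- mid[pcombo$i0[grid$pc[g]]]
      p1 <- mid[pcombo$i1[grid$pc[g]]]
      p2 <- max(0, 1 - p0 - p1)  # triangle boundary can round below zero
      lw <- log(c(p0, p1, p2))
      lf <- rbind(log_f[grid$iw0[g], ], log_f[d + 1L, ], log_f[d + 1L + grid$iw2[g], ]) + lw
      m <- apply(lf, 2L, max)
      site_ll <- m + log(colSums(exp(sweep(lf, 2L, m, "-"))))
      logfXg[g] <- sum(fd$weights * site_ll)
      pos_site[g, ] <- exp(lf[3, ] - site_ll)
    }
    mg <- max(logfXg)
    wg <- exp(logfXg - mg)
    pp_pat <- colSums(wg * pos_site) / sum(wg)
  } else {  # M8
    p0_grid <- mid
    pq_grid <- exp(seq(log(0.05), log(20), length.out = d))  # shape grids
    ws_grid <- 1 + mid * 10
    # distinct omega values: beta category means per (p, q) combo + ws grid
    beta_means <- array(NA_real_, c(d, d, fit$ncat))
    for (i in seq_len(d)) for (j in seq_len(d)) {
      beta_means[i, j, ] <- beta_category_means(pq_grid[i], pq_grid[j], fit$ncat)
    }
    omegas <- c(as.vector(beta_means), ws_grid)
    log_f <- .grid_site_logliks(fd, kappa, omegas, scale,
                                ref_omegas = fit$classes$omega,
                                ref_weights = fit$classes$weight)
    npat <- fd$npat
    nbm <- d * d * fit$ncat
    logfXg <- numeric(d * d * d * d)
    pos_site <- matrix(0, length(logfXg), npat)
    g <- 0L
    for (i0 in seq_len(d)) for (ip in seq_len(d)) for (iq in seq_len(d)) {
      # rows of log_f for the 10 beta categories of this (p, q)
      rows <- ((seq_len(fit$ncat) - 1L) * d * d) + (iq - 1L) * d + ip
      for (iws in seq_len(d)) {
        g <- g + 1L
        p0 <- p0_grid[i0]
        lw <- log(c(rep(p0 / fit$ncat, fit$ncat), 1 - p0))
        lf <- rbind(log_f[rows, , drop = FALSE], log_f[nbm + iws, ]) + lw
        m <- apply(lf, 2L, max)
        site_ll <- m + log(colSums(exp(sweep(lf, 2L, m, "-"))))
        logfXg[g] <- sum(fd$weights * site_ll)
        pos_site[g, ] <- exp(lf[fit$ncat + 1L, ] - site_ll)
      }
    }
    mg <- max(logfXg)
    wg <- exp(logfXg - mg)
    pp_pat <- colSums(wg * pos_site) / sum(wg)
  }
  pp_pat[fd$pat_of_site]
}

# site (pattern) log-likelihood for each omega in a vector, under the flux
# normalization implied by the fitted model's classes
.grid_site_logliks <- function(fd, kappa, omegas, scale, ref_omegas, ref_weights) {
  ref_Q <- lapply(ref_omegas, .codon_Q, kappa = kappa, pi = fd$pi)
  flux <- sum(ref_weights * vapply(ref_Q, `[[`, numeric(1), "flux"))
  el <- fd$post$edge.length * scale / flux
  out <- matrix(NA_real_, length(omegas), fd$npat)
  for (k in seq_along(omegas)) {
    Qk <- .codon_Q(kappa, omegas[k], fd$pi)
    eig <- .eigen_Q(Qk, fd$pi)
    Plist <- lapply(el, .prob_matrix, eig = eig)
    out[k, ] <- .prune_class(fd, Plist)
  }
  out
}
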