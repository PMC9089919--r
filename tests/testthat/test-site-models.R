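# Codon site models: likelihood correctness against the dense
# matrix-exponential oracle, nested-model behaviour, posteriors, LRTs and
# selected-site identification.

test_that("likelihood of identical sequences on zero branches is the root prior", {
  aln <- c(a = "TTTGGGAAA", b = "TTTGGGAAA")
  tr <- ape::read.tree(text = "(a:0,b:0);")
  fit <- fit_site_model(aln, tr, model = "M0", freq = "equal", restarts = 1,
                        seed = 1)
  expect_equal(fit$lnL, 3 * log(1 / 61), tolerance = 1e-6)
})

test_that("pruning likelihood matches the matrix-exponential oracle on toys", {
  tr3 <- ape::read.tree(text = "(a:0.3,b:0.1,c:0.25);")
  sim3 <- simulate_codon_alignment(tr3, 12, kappa = 3, omegas = 0.7, seed = 5)
  tr2 <- ape::read.tree(text = "(a:0.2,b:0.15);")
  sim2 <- simulate_codon_alignment(tr2, 8, kappa = 2, omegas = 2, seed = 6)
  pi_eq <- rep(1 / 61, 61)
  set.seed(8)
  pi_rnd <- runif(61, 0.5, 2); pi_rnd <- pi_rnd / sum(pi_rnd)

  cases <- list(
    list(aln = sim3$aln, tree = tr3, kappa = 3, omega = 0.7, pi = pi_eq, scale = 1),
    list(aln = sim3$aln, tree = tr3, kappa = 2.2, omega = 1.8, pi = pi_rnd, scale = 1.3),
    list(aln = sim2$aln, tree = tr2, kappa = 2, omega = 2, pi = pi_eq, scale = 1),
    list(aln = sim2$aln, tree = tr2, kappa = 0.5, omega = 0.1, pi = pi_rnd, scale = 0.4))
  for (cs in cases) {
    expect_equal(
      package_codon_lnL(cs$aln, cs$tree, cs$kappa, cs$omega, cs$pi, cs$scale),
      oracle_codon_lnL(cs$aln, cs$tree, cs$kappa, cs$omega, cs$pi, cs$scale),
      tolerance = 1e-8)
  }
})

test_that("nested models dominate and M2a collapses to M1a at p2 = 0", {
  tr <- balanced_sim_tree(8, 0.75)
  sim <- simulate_codon_alignment(tr, 80, kappa = 2, omegas = c(0.1, 1, 3),
                                  weights = c(0.6, 0.3, 0.1), seed = 21)
  f1 <- fit_site_model(sim$aln, tr, model = "M1a", restarts = 1, seed = 1,
                       freq = "equal")
  f2 <- fit_site_model(sim$aln, tr, model = "M2a", restarts = 2, seed = 1,
                       freq = "equal")
  f7 <- fit_site_model(sim$aln, tr, model = "M7", restarts = 1, seed = 1,
                       freq = "equal")
  f8 <- fit_site_model(sim$aln, tr, model = "M8", restarts = 1, seed = 1,
                       freq = "equal")
  expect_gte(f2$lnL, f1$lnL - 1e-4)
  expect_gte(f8$lnL, f7$lnL - 1e-4)

  # engine consistency: M2a class structure with p2 = 0 equals M1a's lnL
  pi_v <- codon_frequencies(sim$aln, "equal")
  fd <- drbdiv:::.codon_fit_data(sim$aln, tr, pi_v)
  p <- f1$params
  lf1 <- drbdiv:::.class_logliks(fd, p$kappa, c(p$omega0, 1), c(p$p0, p$p1),
                                 p$scale)
  l_m1a <- drbdiv:::.mixture_loglik(fd, lf1, c(p$p0, p$p1))
  lf2 <- drbdiv:::.class_logliks(fd, p$kappa, c(p$omega0, 1, 5),
                                 c(p$p0, p$p1, 0), p$scale)
  l_m2a0 <- drbdiv:::.mixture_loglik(fd, lf2, c(p$p0, p$p1, 0))
  expect_equal(l_m1a, f1$lnL, tolerance = 1e-8)
  expect_equal(l_m2a0, l_m1a, tolerance = 1e-6)

  # per-site posterior rows sum to one
  expect_true(all(abs(rowSums(f2$posteriors) - 1) < 1e-10))
  expect_true(all(abs(rowSums(f8$posteriors) - 1) < 1e-10))
})

test_that("likelihood ratio test uses the chi-square closed form", {
  fake <- function(model, lnL) structure(list(model = model, lnL = lnL),
                                         class = "site_model_fit")
  eq <- likelihood_ratio_test(fake("M1a", -100), fake("M2a", -100))
  expect_equal(eq$delta, 0)
  expect_equal(eq$p, 1)

  lrt <- likelihood_ratio_test(fake("M1a", -100), fake("M2a", -100 + 10.34 / 2))
  expect_equal(lrt$delta, 10.34)
  expect_equal(lrt$p, exp(-10.34 / 2), tolerance = 1e-12)
  expect_lt(lrt$p, 0.01)

  expect_error(likelihood_ratio_test(fake("M7", -10), fake("M2a", -9)),
               "not nested")
})

test_that("selected-site identification requires a positive class", {
  tr <- balanced_sim_tree(4, 0.5)
  sim <- simulate_codon_alignment(tr, 30, kappa = 2, omegas = 0.5, seed = 31)
  f1 <- fit_site_model(sim$aln, tr, model = "M1a", restarts = 1, seed = 1,
                       freq = "equal")
  expect_error(identify_selected_sites(f1), "positive-selection class")
})

test_that("invariant alignments yield no selected sites", {
  one <- paste(rep("GTACCT", 10), collapse = "")
  aln <- c(a = one, b = one, c = one, d = one)
  tr <- balanced_sim_tree(4, 0.3)
  tr$tip.label <- names(aln)
  f2 <- fit_site_model(aln, tr, model = "M2a", restarts = 1, seed = 1,
                       freq = "equal")
  sel <- identify_selected_sites(f2, threshold = 0.95)
  expect_equal(nrow(sel), 0L)
})

test_that("BEB and NEB agree on a strong positive-selection signal", {
  tr <- balanced_sim_tree(8, 1.0)
  cls <- c(rep(2, 4), rep(1, 26))
  sim <- simulate_codon_alignment(tr, 30, kappa = 2, omegas = c(0.1, 5),
                                  site_classes = cls, seed = 77)
  f2 <- fit_site_model(sim$aln, tr, model = "M2a", restarts = 2, seed = 3,
                       freq = "equal")
  neb <- identify_selected_sites(f2, threshold = 0.9, method = "NEB")
  beb <- identify_selected_sites(f2, threshold = 0.9, method = "BEB")
  pp_beb <- attr(beb, "all_posteriors")
  pp_neb <- attr(neb, "all_posteriors")
  expect_true(all(is.finite(pp_beb)))
  expect_true(all(pp_beb >= 0 & pp_beb <= 1))
  # the two methods rank the same codons at the top
  expect_gte(length(intersect(order(-pp_beb)[1:4], order(-pp_neb)[1:4])), 3L)
  # and the top-ranked codons are dominated by the truly selected ones
  expect_gte(sum(order(-pp_neb)[1:4] %in% 1:4), 2L)
})
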