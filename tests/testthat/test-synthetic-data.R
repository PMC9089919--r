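# Synthetic allele pools, genotypes and clone sets: invariants and
# calibration of the generators.

test_that("allele pool meets its structural invariants", {
  pool <- simulate_allele_pool(1, 0, seed = 1)
  expect_length(pool$functional, 1L)
  expect_equal(nchar(pool$functional[[1]]), 242L)
  expect_false(any(is_stop_codon(inframe_codons(pool$functional[[1]], 2))))

  pool <- simulate_allele_pool(11, 3, n_codons = 80, seed = 42)
  expect_equal(unique(nchar(pool$functional)), 242L)
  expect_equal(unique(nchar(pool$pseudogene)), 241L)
  expect_silent(validate_allele_pool(pool))
  # every pseudogene is one deletion away from a functional allele
  expect_equal(nrow(pool$deletions), 3L)
})

test_that("impossible pool parameters are reported as unsatisfiable", {
  expect_error(simulate_allele_pool(3, 0, target_divergence = 0, seed = 1),
               "unsatisfiable")
  expect_error(simulate_allele_pool(0, 0, seed = 1), "n_functional")
  expect_error(simulate_allele_pool(3, 0, target_divergence = 0.7, seed = 1),
               "target_divergence")
})

test_that("pool divergence calibration hits the target on average", {
  realized <- vapply(seq_len(200), function(s) {
    pool_mean_p_distance(simulate_allele_pool(8, 0, target_divergence = 0.05,
                                              seed = s))
  }, numeric(1))
  expect_gt(mean(realized), 0.04)
  expect_lt(mean(realized), 0.06)
})

test_that("genotype simulation respects degenerate frequencies and linkage", {
  pool <- simulate_allele_pool(6, 3, seed = 5)
  fn <- names(pool$functional)
  # single allele at frequency 1: everyone carries exactly it
  freqs <- list(east = list(l1 = stats::setNames(1, fn[1])))
  truth <- simulate_genotypes(pool, freqs, c(east = 20L), seed = 9)
  expect_true(all(vapply(truth$alleles, identical, logical(1), y = fn[1])))

  # linked pair never separates
  pair <- paste0(fn[2], "+", fn[3])
  freqs2 <- list(east = list(
    l1 = stats::setNames(c(0.6, 0.4), c(fn[1], "(none)")),
    l2 = stats::setNames(c(0.5, 0.5), c(pair, "(none)"))))
  truth2 <- simulate_genotypes(pool, freqs2, c(east = 60L),
                               linkage_pairs = list(c(fn[2], fn[3])), seed = 10)
  solo <- vapply(truth2$alleles, function(al) xor(fn[2] %in% al, fn[3] %in% al),
                 logical(1))
  expect_equal(sum(solo), 0L)

  # unknown allele names are rejected
  expect_error(simulate_genotypes(
    pool, list(east = list(l1 = c(NOPE = 1))), c(east = 2L), seed = 1),
    "unknown allele")
})

test_that("carrier proportions follow binomial sampling across subpopulations", {
  pool <- simulate_allele_pool(6, 0, seed = 2)
  fn <- names(pool$functional)
  freqs <- list(
    east = list(l1 = stats::setNames(c(0.9, 0.1), fn[1:2])),
    north = list(l1 = stats::setNames(c(0.1, 0.9), fn[1:2])))
  truth <- simulate_genotypes(pool, freqs, c(east = 200L, north = 200L), seed = 11)
  sp <- truth$individuals$subpop
  carA <- vapply(truth$alleles[truth$individuals$individual_id],
                 function(al) fn[1] %in% al, logical(1))
  for (s in c("east", "north")) {
    p_hap <- if (s == "east") 0.9 else 0.1
    p_carrier <- 1 - (1 - p_hap)^2
    x <- sum(carA[sp == s])
    expect_gte(x, stats::qbinom(0.005, 200, p_carrier))
    expect_lte(x, stats::qbinom(0.995, 200, p_carrier))
  }
})

test_that("noise-free clones are exact copies of true alleles", {
  sim <- simulate_wolverine_cohort(seed = 21, error_rate = 0, chimera_rate = 0)
  truth_seqs <- c(sim$pool$functional, sim$pool$pseudogene)
  expect_true(all(sim$clones$seq %in% truth_seqs))
  for (r in seq_len(nrow(sim$truth$individuals))) {
    id <- sim$truth$individuals$individual_id[r]
    own <- truth_seqs[sim$truth$alleles[[id]]]
    expect_true(all(sim$clones$seq[sim$clones$individual_id == id] %in% own))
  }
  expect_true(all(sim$clones$provenance == "faithful"))
})

test_that("clone counts and chimera fractions match their sampling models", {
  sim <- simulate_wolverine_cohort(seed = 33)
  # 32 individuals at mean 26.9: total within 10% of 861
  expect_gt(nrow(sim$clones), 0.9 * 861)
  expect_lt(nrow(sim$clones), 1.1 * 861)
  # provenance partitions the clone set
  expect_equal(sum(table(sim$clones$provenance)), nrow(sim$clones))
  expect_true(all(sim$clones$provenance %in% c("faithful", "point_error", "chimera")))

  # chimeric fraction calibration on two-allele individuals
  pool <- simulate_allele_pool(2, 0, seed = 3)
  fn <- names(pool$functional)
  freqs <- list(east = list(
    l1 = stats::setNames(1, fn[1]), l2 = stats::setNames(1, fn[2])))
  truth <- simulate_genotypes(pool, freqs, c(east = 400L), seed = 4)
  clones <- simulate_clones(truth, mean_clones = 25, error_rate = 0,
                            chimera_rate = 0.1, seed = 5)
  frac <- mean(clones$provenance == "chimera")
  expect_gt(frac, 0.09)
  expect_lt(frac, 0.11)
})

test_that("chimeras on single-allele individuals are downgraded and logged", {
  pool <- simulate_allele_pool(2, 0, seed = 6)
  fn <- names(pool$functional)
  truth <- simulate_genotypes(
    pool, list(east = list(l1 = stats::setNames(1, fn[1]))), c(east = 30L),
    seed = 7)
  clones <- simulate_clones(truth, mean_clones = 20, error_rate = 0,
                            chimera_rate = 0.5, seed = 8)
  expect_true(all(clones$provenance == "faithful"))
  expect_gt(length(attr(clones, "downgraded_chimeras")), 0L)
})

test_that("identical seeds reproduce byte-identical FASTA output", {
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_clone_fasta(simulate_wolverine_cohort(seed = 12)$clones, f1)
  write_clone_fasta(simulate_wolverine_cohort(seed = 12)$clones, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
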