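# K80 distances, neighbor joining, cross-species allele sharing and
# species-monophyly tests.

test_that("K80 distance matches its closed form and flags saturation", {
  s0 <- paste(rep("A", 100), collapse = "")
  expect_equal(k80_distance(s0, s0)$d, 0)

  s_ts <- paste(c(rep("G", 10), rep("A", 90)), collapse = "")
  k1 <- k80_distance(s0, s_ts)
  expect_equal(k1$P, 0.1); expect_equal(k1$Q, 0)
  expect_equal(k1$d, 0.11157, tolerance = 1e-4)

  s_tv <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  k2 <- k80_distance(s0, s_tv)
  expect_equal(k2$P, 0); expect_equal(k2$Q, 0.1)
  # -1/2 log(0.9) - 1/4 log(0.8), frozen from the closed form
  expect_equal(k2$d, 0.108465, tolerance = 1e-4)

  sat <- paste(rep(c("A", "G"), 50), collapse = "")
  satB <- paste(rep(c("G", "A"), 50), collapse = "")
  expect_true(k80_distance(sat, satB)$saturated)

  # gap and ambiguity columns excluded pairwise
  g1 <- "AC-GTN"; g2 <- "ACTGTA"
  expect_equal(k80_distance(g1, g2)$sites_used, 4L)
})

test_that("K80 agrees with the ape oracle on simulated alignments", {
  pool <- simulate_allele_pool(6, 0, n_codons = 40, seed = 3,
                               target_divergence = 0.12)
  aln <- pool$functional
  dm <- k80_distance_matrix(aln)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(unname(aln), "")))
  rownames(bin) <- names(aln)
  da <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(dm$d, da[rownames(dm$d), colnames(dm$d)], tolerance = 1e-10)
})

test_that("K80 distance is monotone in P and in Q", {
  for (Q in c(0, 0.05, 0.1)) {
    ds <- vapply(seq(0, 0.3, by = 0.05), function(P) {
      arg1 <- 1 - 2 * P - Q
      s0 <- paste(rep("A", 100), collapse = "")
      s1 <- paste(c(rep("G", round(100 * P)), rep("C", round(100 * Q)),
                    rep("A", 100 - round(100 * P) - round(100 * Q))),
                  collapse = "")
      k80_distance(s0, s1)$d
    }, numeric(1))
    expect_true(all(diff(ds) > 0))
  }
})

test_that("neighbor joining is exact on additive matrices", {
  tr <- ape::read.tree(
    text = "((a:0.1,b:0.2):0.05,(c:0.3,d:0.15):0.07,e:0.22);")
  D <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(D)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
               tolerance = 1e-10)
  expect_equal(ape::dist.topo(ape::unroot(nj), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
})

test_that("three-taxon branch lengths solve the pairwise equations", {
  D <- matrix(c(0, 0.3, 0.4, 0.3, 0, 0.5, 0.4, 0.5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nj <- neighbor_joining(D)
  cp <- ape::cophenetic.phylo(nj)
  expect_equal(cp[rownames(D), colnames(D)], D, tolerance = 1e-10)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining recovers ultrametric topology and matches ape", {
  # ultrametric 4-taxon: ((a,b),(c,d)) with clean depth structure
  D <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 3,
                6, 6, 3, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  nj <- neighbor_joining(D)
  split_ab <- ape::getMRCA(ape::root(nj, "d"), c("a", "b"))
  expect_setequal(
    ape::extract.clade(ape::root(nj, "d"), split_ab)$tip.label, c("a", "b"))

  set.seed(12)
  for (i in 1:5) {
    tr <- random_test_tree(7, 100 + i)
    D2 <- ape::cophenetic.phylo(tr)
    mine <- neighbor_joining(D2)
    apes <- ape::nj(stats::as.dist(D2))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(apes)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("identical allele grouping partitions input and flags cross-species shares", {
  al <- c("SpA|x1" = "ACGTACGTACGTACGTACGTACGTACGTAC",
          "SpB|y1" = "ACGTACGTACGTACGTACGTACGTACGTAC",
          "SpA|x2" = "TTGTACGTACGTACGTACGTACGTACGTAC")
  g <- identical_allele_groups(al, "full")
  expect_length(g, 2L)
  big <- g[[which(vapply(g, nrow, integer(1)) == 2L)]]
  expect_setequal(big$species, c("SpA", "SpB"))
  expect_true(attr(big, "tsp_detected"))
  expect_equal(sum(vapply(g, nrow, integer(1))), length(al))

  # trimmed rule: a 185-nt record groups with the 242-nt allele containing it
  pool <- simulate_allele_pool(3, 0, seed = 44, target_divergence = 0.2)
  full <- pool$functional[[1]]
  short <- substr(full, 30, 214)
  al2 <- c(al1 = full, al2short = short, other = pool$functional[[2]])
  names(al2) <- c("SpA|a1", "SpB|b1", "SpC|c1")
  g2 <- identical_allele_groups(al2, "trimmed")
  sizes <- vapply(g2, nrow, integer(1))
  expect_setequal(sizes, c(2L, 1L))
  expect_error(identical_allele_groups(character(0)), "empty")
})

test_that("species monophyly matches the rooted-clade oracle on random trees", {
  t1 <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  sp <- stats::setNames(c("A", "A", "B", "B"), c("a1", "a2", "b1", "b2"))
  m1 <- species_monophyly(t1, sp)
  expect_true(all(m1$monophyletic))
  expect_false(attr(m1, "tsp_detected"))

  t2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  m2 <- species_monophyly(t2, sp)
  expect_false(any(m2$monophyletic))
  expect_true(attr(m2, "tsp_detected"))

  for (i in 1:12) {
    tr <- random_test_tree(6, 200 + i)
    set.seed(300 + i)
    spp <- stats::setNames(sample(c("A", "A", "A", "B", "B", "C")),
                           tr$tip.label)
    res <- species_monophyly(tr, spp)
    for (s in c("A", "B")) {
      tips_s <- names(spp)[spp == s]
      expect_equal(res$monophyletic[res$species == s],
                   oracle_monophyletic(tr, tips_s),
                   info = paste("tree", i, "species", s))
    }
    expect_true(res$vacuous[res$species == "C"])
  }
})
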