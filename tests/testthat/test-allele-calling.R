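# Clone collapsing, the two-detection validation rule, the ORF classifier,
# allele naming and the genotype matrix.

mini_clones <- function(rows) {
  as_clone_set(do.call(rbind, lapply(rows, function(r) {
    data.frame(individual_id = r[[1]], clone_id = r[[2]], seq = r[[3]],
               stringsAsFactors = FALSE)
  })))
}

test_that("collapse_clones groups identical sequences and conserves support", {
  cl <- mini_clones(list(
    list("IND1", "clone1", "ACGT"), list("IND1", "clone2", "ACGT"),
    list("IND1", "clone3", "ACGT"), list("IND2", "clone1", "ACGA")))
  cands <- collapse_clones(cl)
  expect_length(cands, 2L)  # sequences one base apart stay distinct
  first <- cands[[which(vapply(cands, `[[`, "", "seq") == "ACGT")]]
  expect_equal(first$total_support, 3L)
  expect_equal(first$support[["IND1"]], 3L)
  expect_equal(sum(vapply(cands, `[[`, integer(1), "total_support")), nrow(cl))

  # support totals also conserved on a full simulated cohort
  sim <- simulate_wolverine_cohort(seed = 2)
  cands2 <- collapse_clones(sim$clones)
  expect_equal(sum(vapply(cands2, `[[`, integer(1), "total_support")),
               nrow(sim$clones))
})

test_that("validation implements the two-detection rule exactly", {
  cl <- mini_clones(list(
    list("IND1", "clone1", "AAAA"), list("IND1", "clone2", "AAAA"),  # twice, one ind
    list("IND1", "clone3", "CCCC"), list("IND2", "clone1", "CCCC"),  # once each, two inds
    list("IND3", "clone1", "GGGG")))                                  # singleton
  val <- validate_candidates(collapse_clones(cl))
  vseqs <- vapply(val$validated, `[[`, "", "seq")
  expect_setequal(vseqs, c("AAAA", "CCCC"))
  expect_equal(vapply(val$rejected_singletons, `[[`, "", "seq"), "GGGG")
  # partition is exhaustive and idempotent
  expect_equal(length(val$validated) + length(val$rejected_singletons), 3L)
  again <- validate_candidates(val$validated)
  expect_identical(again$validated, val$validated)
  expect_length(again$rejected_singletons, 0L)
})

test_that("classifier handles the worked amplicon cases", {
  # 242 nt, stop-free in frame: functional
  fun242 <- paste0("CA", paste(rep("GTA", 80), collapse = ""))
  cl <- classify_sequence(fun242)
  expect_equal(cl$status, "functional")
  expect_false(cl$orf_report$indel_detected)
  expect_length(cl$orf_report$premature_stop_positions, 0L)

  # one-base deletion: 241 nt, frameshift creates premature stops
  del241 <- paste0(substr(fun242, 1, 2), substr(fun242, 4, 242))
  cl2 <- classify_sequence(del241)
  expect_equal(cl2$status, "pseudogene")
  expect_true(cl2$orf_report$indel_detected)
  expect_gt(length(cl2$orf_report$premature_stop_positions), 0L)

  # full-length but with TAA at codon 10: pseudogene by premature stop
  codons <- rep("GTA", 80); codons[10] <- "TAA"
  stop242 <- paste0("CA", paste(codons, collapse = ""))
  cl3 <- classify_sequence(stop242)
  expect_equal(cl3$status, "pseudogene")
  expect_equal(cl3$orf_report$premature_stop_positions, 10L)
  expect_false(cl3$orf_report$indel_detected)

  # non-target amplicon lengths are rejected
  expect_error(classify_sequence(substr(fun242, 1, 230)), "non-target")
})

test_that("classifier agrees with a translate-and-scan oracle on 242-nt inputs", {
  set.seed(99)
  for (i in seq_len(60)) {
    seq <- paste(sample(c("A", "C", "G", "T"), 242, replace = TRUE),
                 collapse = "")
    got <- classify_sequence(seq)$status
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(seq, 3, 242)),
      if.fuzzy.codon = "solve"))
    expect_equal(got, if (grepl("*", aa, fixed = TRUE)) "pseudogene" else "functional")
  }
})

test_that("indel localization finds the deleted base region", {
  pool <- simulate_allele_pool(4, 1, seed = 13)
  ps <- pool$pseudogene[[1]]
  cl <- classify_sequence(ps, reference_alleles = pool$functional)
  expect_equal(cl$status, "pseudogene")
  expect_true(is.finite(cl$orf_report$indel_position))
  # alignment gap within a few bases of the true deletion (ambiguous in runs)
  expect_lt(abs(cl$orf_report$indel_position - pool$deletions$position[1]), 8)
})

test_that("allele naming orders by carrier count with stable ties", {
  mk <- function(seq, inds, status) {
    list(seq = seq, support = stats::setNames(rep(1L, length(inds)), inds),
         total_support = length(inds), status = status)
  }
  cand <- list(mk("AAA", c("I1", "I2"), "functional"),
               mk("CCC", c("I1", "I2", "I3"), "functional"),
               mk("GGG", c("I4", "I5"), "functional"),
               mk("TTT", "I1", "pseudogene"),
               mk("TTA", c("I1", "I2"), "pseudogene"))
  named <- name_alleles(cand, prefix = "Gugu")
  nm <- vapply(named, `[[`, "", "name")
  sq <- vapply(named, `[[`, "", "seq")
  expect_equal(sq[nm == "Gugu-DRB*01"], "CCC")   # most carriers first
  expect_equal(sq[nm == "Gugu-DRB*02"], "AAA")   # tie broken by input order
  expect_equal(sq[nm == "Gugu-DRB*03"], "GGG")
  expect_equal(sq[nm == "Gugu-DRB*PS01"], "TTA")
  expect_identical(nm, vapply(name_alleles(cand, "Gugu"), `[[`, "", "name"))
})

test_that("genotype matrix construction enforces labels and flags empty rows", {
  alleles <- c(`G-DRB*01` = "AAAA")
  attr(alleles, "status") <- c(`G-DRB*01` = "functional")
  cl <- mini_clones(list(list("IND1", "clone1", "AAAA"),
                         list("IND2", "clone1", "CCCC")))
  expect_error(build_genotype_matrix(alleles, cl, c(IND1 = "east")), "IND2")
  expect_warning(
    gm <- build_genotype_matrix(alleles, cl, c(IND1 = "east", IND2 = "north")),
    "IND2")
  expect_true(gm$presence["IND1", 1])
  expect_false(gm$presence["IND2", 1])
})

test_that("noise-free simulated clones are recovered exactly", {
  sim <- simulate_wolverine_cohort(seed = 17, error_rate = 0, chimera_rate = 0)
  labels <- stats::setNames(sim$truth$individuals$subpop,
                            sim$truth$individuals$individual_id)
  res <- call_alleles(sim$clones, labels)
  truth_seqs <- sort(unname(c(sim$pool$functional, sim$pool$pseudogene)))
  # every allele present in >= 1 clone is recoverable; with ~27 clones per
  # individual every carried allele is seen at least twice
  carried <- unique(unlist(sim$truth$alleles))
  expect_setequal(unname(res$alleles),
                  unname(c(sim$pool$functional, sim$pool$pseudogene)[carried]))
  st <- attr(res$alleles, "status")
  expect_true(all(res$alleles[st == "functional"] %in% sim$pool$functional))
  expect_true(all(res$alleles[st == "pseudogene"] %in% sim$pool$pseudogene))
})
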