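# Trans-species polymorphism toolkit: Kimura two-parameter distances,
# neighbor joining (with explicit negative-branch handling), exact-match
# allele sharing across species, and species-monophyly tests on the
# unrooted tree.

#' Kimura two-parameter distance between two aligned sequences
#'
#' Columns where either sequence has a gap or ambiguity code are excluded
#' pairwise. `d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))` with P and Q the
#' transition and transversion proportions; saturated pairs (non-positive
#' log argument) are flagged infinite.
#'
#' @param seqA,seqB Aligned DNA strings of equal length.
#' @param gamma_alpha Optional gamma shape; when supplied the K80+Gamma
#'   correction is applied instead.
#' @return List with `d`, `P`, `Q`, `sites_used`, `saturated`.
#' @export
k80_distance <- function(seqA, seqB, gamma_alpha = NULL) {
  if (nchar(seqA) != nchar(seqB)) stop("aligned sequences must have equal length")
  a <- strsplit(toupper(seqA), "")[[1]]
  b <- strsplit(toupper(seqB), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no comparable gap-free columns")
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  diff <- a != b
  ts <- diff & (purine[a] == purine[b])
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    return(list(d = Inf, P = P, Q = Q, sites_used = n, saturated = TRUE))
  }
  d <- if (is.null(gamma_alpha)) {
    -0.5 * log(arg1) - 0.25 * log(arg2)
  } else {
    al <- gamma_alpha
    (al / 2) * (arg1^(-1 / al) + 0.5 * arg2^(-1 / al) - 1.5)
  }
  list(d = d, P = P, Q = Q, sites_used = n, saturated = FALSE)
}

#' K80 distance matrix for an aligned sequence set
#'
#' @param aln Named character vector of aligned sequences.
#' @param gamma_alpha Optional gamma shape for K80+Gamma.
#' @return A `dist_k80`: list(taxa, d, P, Q) of symmetric matrices.
#' @export
k80_distance_matrix <- function(aln, gamma_alpha = NULL) {
  n <- length(aln)
  taxa <- names(aln)
  d <- P <- Q <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    k <- k80_distance(aln[[i]], aln[[j]], gamma_alpha)
    d[i, j] <- d[j, i] <- k$d
    P[i, j] <- P[j, i] <- k$P
    Q[i, j] <- Q[j, i] <- k$Q
  }
  structure(list(taxa = taxa, d = d, P = P, Q = Q), class = "dist_k80")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration. A negative branch length produced by the
#' length equations is clamped to zero with the deficit moved to the sibling
#' branch, preserving the pair's summed length.
#'
#' @param D A `dist_k80`, or a symmetric numeric matrix with dimnames.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  d <- if (inherits(D, "dist_k80")) D$d else as.matrix(D)
  if (is.null(rownames(d))) stop("distance matrix needs taxon names")
  if (any(!is.finite(d))) stop("non-finite distances (saturated pairs?)")
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(d)
  # active nodes represented as newick fragments
  frag <- labels
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    qm <- (m - 2) * d - outer(r, r, "+")
    diag(qm) <- Inf
    ij <- which(qm == min(qm), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], li, frag[j], lj)
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    dn <- dn[-c(i, j)]
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, dn), c(dn, 0))
    frag <- c(frag[-c(i, j)], newfrag)
  }
  # resolve the final three nodes around the central vertex
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ls <- c(la, lb, lc)
  ls[ls < 0] <- 0
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], ls[1], frag[2], ls[2], frag[3], ls[3])
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree directly from sequences
#'
#' K80 distances followed by [neighbor_joining()].
#'
#' @param aln Named character vector of aligned sequences.
#' @return An `ape::phylo`.
#' @export
nj_tree_from_sequences <- function(aln) {
  neighbor_joining(k80_distance_matrix(aln))
}

#' Group alleles with identical sequences across species
#'
#' Under `overlap_rule = "full"` two records group iff their sequences are
#' identical. Under `"trimmed"`, records of different length group when the
#' shorter sequence occurs exactly as a substring of the longer (comparison
#' over the shared window); grouping is the transitive closure.
#'
#' @param alleles Named character vector of sequences; names `Species|Allele`
#'   (an optional third `|Accession` field is allowed).
#' @param overlap_rule "full" or "trimmed".
#' @return List of groups; each group is a data.frame(species, allele).
#'   Groups spanning >= 2 species carry attribute `tsp_detected = TRUE`. The result
#'   partitions the input (attribute `n_input`).
#' @export
identical_allele_groups <- function(alleles, overlap_rule = c("full", "trimmed")) {
  overlap_rule <- match.arg(overlap_rule)
  if (length(alleles) == 0L) stop("empty input")
  meta <- strsplit(names(alleles), "|", fixed = TRUE)
  species <- vapply(meta, `[[`, "", 1L)
  allele <- vapply(meta, function(x) if (length(x) >= 2L) x[[2L]] else x[[1L]], "")
  n <- length(alleles)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(x, y) { parent[find(x)] <<- find(y) }
  match_fun <- if (overlap_rule == "full") {
    function(a, b) a == b
  } else {
    function(a, b) {
      if (nchar(a) == nchar(b)) return(a == b)
      if (nchar(a) < nchar(b)) grepl(a, b, fixed = TRUE) else grepl(b, a, fixed = TRUE)
    }
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (match_fun(alleles[[i]], alleles[[j]])) union_(i, j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- lapply(split(seq_len(n), roots), function(ix) {
    g <- data.frame(species = species[ix], allele = allele[ix],
                    stringsAsFactors = FALSE)
    attr(g, "tsp_detected") <- length(unique(g$species)) >= 2L
    g
  })
  names(groups) <- NULL
  attr(groups, "n_input") <- n
  groups
}

#' Species-monophyly test on an unrooted tree
#'
#' A species is monophyletic iff some bipartition of the unrooted tree
#' separates exactly its tips from everything else. Trans-species
#' polymorphism is flagged when any species with at least two tips is not
#' monophyletic.
#'
#' @param tree An `ape::phylo`.
#' @param species_of Named character vector mapping tip label -> species.
#' @return data.frame(species, n_tips, monophyletic, vacuous) with attribute
#'   `tsp_detected` (logical).
#' @export
species_monophyly <- function(tree, species_of) {
  tips <- tree$tip.label
  miss <- setdiff(tips, names(species_of))
  if (length(miss)) stop("tips without species: ", paste(miss, collapse = ", "))
  sp <- species_of[tips]
  if (length(unique(sp)) < 2L) stop("need at least 2 species on the tree")
  bip <- .tree_bipartitions(tree)
  res <- do.call(rbind, lapply(sort(unique(unname(sp))), function(s) {
    stips <- sort(tips[sp == s])
    nts <- length(stips)
    if (nts == 1L) {
      return(data.frame(species = s, n_tips = 1L, monophyletic = TRUE,
                        vacuous = TRUE, stringsAsFactors = FALSE))
    }
    mono <- any(vapply(bip, function(side) {
      identical(side, stips) || identical(sort(setdiff(tips, side)), stips)
    }, logical(1)))
    data.frame(species = s, n_tips = nts, monophyletic = mono,
               vacuous = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "tsp_detected") <- any(!res$monophyletic & res$n_tips >= 2L)
  res
}

# tip sets on one side of every edge (trivial single-tip sides included)
.tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + post$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; ch <- post$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  lapply(post$edge[, 2], function(ch) sort(below[[ch]]))
}
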