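---
title: "Methods: clone-based DRB genotyping and selection analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone-based DRB genotyping and selection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drbdiv)
```

## The problem

`drbdiv` analyses major histocompatibility complex (MHC) class II *DRB*
exon 2 diversity in a wild mustelid population genotyped by plasmid cloning
of a 242-nt amplicon. Exon 2 encodes the β1 domain of the DR β-chain, which
lines the peptide-binding groove; it is the classic target for studying
balancing and positive selection in wildlife. Because the amplicon
co-amplifies several paralogous loci, genotypes are *presence/absence* sets
of alleles per individual rather than diploid genotypes at a single locus,
and raw clone sequences carry PCR artifacts (point errors and template
switching chimeras) that must be filtered before any inference.

The pipeline covers five stages: allele calling from clones, subpopulation
statistics on the genotype matrix, dN/dS partitioned by antigen-binding
sites, codon site models with likelihood ratio tests, and trans-species
polymorphism (TSP) detection. A synthetic-data module generates cohorts
with full ground truth so every stage can be tested for recovery.

## Allele calling

Clones are collapsed exactly (no clustering); a candidate sequence is
**validated** iff it was observed at least twice — twice in one individual,
or once each in at least two individuals. Singletons are discarded as
likely PCR artifacts. This is the standard clone-validation rule for MHC
studies; it is deliberately conservative and is the *only* chimera defence
(explicit chimera detection is out of scope). Its known weakness — a
recurrent chimera of the same two parents can be seen twice and pass — is
discussed under *Limitations*.

A validated sequence is **functional** iff it has the expected amplicon
length (242 nt by default) and its reading frame contains no stop codon;
otherwise it is a **pseudogene**, with the indel localized by global
alignment (match +1, mismatch −1, gap −2) against the closest full-length
allele. Only the length test and stop scan decide status; the alignment is
reporting detail. The reading frame starts after a 2-nt offset, giving 80
complete codons from 242 nt; the offset is configurable but 80 codons is
the geometry all defaults assume.

Allele names follow the field convention `<prefix>-DRB*01` onward by
decreasing carrier count (ties by first observation, so naming is
deterministic), pseudogenes `<prefix>-DRB*PS01` onward. A globally
validated allele observed in even one clone of an individual is assigned to
that individual; per-individual support thresholds are not applied (the
validation is global, and with ~27 clones per individual a carried allele
is essentially never seen only once).

## Subpopulation statistics

The genotype matrix carries north/east/admixed labels; admixed individuals
are merged into the northern subpopulation by default (their geographic
origin) before any contrast. Carrier contrasts use a two-sided Fisher exact
test computed by full hypergeometric enumeration with the probability-mass
rule (a table counts toward p if its probability does not exceed the
observed table's), which is the convention of R's `fisher.test`; the suite
verifies exact agreement with both a factorial enumeration oracle and
`stats::fisher.test` for all margins up to 25. Mean allele counts per
individual are compared with a Welch t test (unequal variances,
Welch–Satterthwaite df), computed from the closed form and verified against
`stats::t.test`. The maximum number of distinct functional alleles in one
individual, m, implies at least ⌈m/2⌉ functional loci per haploid genome.

## dN/dS with the ABS partition

Selection on the β1 domain is summarized by ω = dN/dS computed with
Nei–Gojobori (1986) counting:

* per-codon synonymous site counts from the fates of all single-base
  changes, with changes to stop codons excluded from the denominator at
  each position (so every sense codon contributes s + n = 3 sites);
* differences between codons averaged over all minimal substitution paths
  with equal weights, skipping paths that pass through a stop codon (if
  every path is blocked — possible only for extreme codon pairs — the
  average falls back to all paths);
* Jukes–Cantor correction d = −(3/4)·ln(1 − 4p/3), flagged undefined when
  p ≥ 3/4;
* mean-of-pairs averaging over all unordered allele pairs (not
  concatenation), separately for the full 80 codons, the 18 ABS codons and
  the 62 non-ABS codons.

Standard errors come from a 1000-replicate bootstrap that resamples codon
columns *within* the partition, with a fixed seed. The counting variant
(unweighted pathway averaging, stop-path exclusion, Jukes–Cantor) is the
canonical NG86 choice; other variants (transition weighting, ML counting)
shift estimates by a few percent, which is why cross-study ω comparisons at
the second decimal are not meaningful.

The ABS mask ships as a plain-text list of 18 codon positions (1-based over
the 80 codons) corresponding to the peptide-contact residues of the human
DR β1 domain — the standard proxy when the study species has no solved
structure, and user-overridable (`load_abs_mask()` accepts any file with
one index per line). The true contact set of a non-human DRB may differ;
conclusions that depend on individual mask positions should be checked
against alternative masks.

## Codon site models

`fit_site_model()` fits M0 (one ω), M1a (nearly neutral: ω₀ < 1, ω₁ = 1),
M2a (adds ω₂ ≥ 1), M7 (beta-distributed ω on (0,1), K = 10
equal-probability categories represented by conditional means) and M8 (beta
plus a point mass ωₛ ≥ 1) by maximum likelihood on a fixed topology. The
likelihood is the Felsenstein pruning likelihood over the 61 sense codons
with a GY94-style generator: target-frequency πⱼ times κ for transitions
times ω for nonsynonymous changes, scaled so the mixture-averaged flux is
one expected substitution per codon per unit branch length. Codon
frequencies are F3x4 by default (equal frequencies for toy comparisons).
Matrix exponentials use the symmetric eigendecomposition of the reversible
generator; the test suite pins the whole likelihood path against a dense
`Matrix::expm` oracle on 2- and 3-taxon alignments to 1e-8.

Design choices that were genuinely open:

* **Tree.** No tree is prescribed for these data, so the default is the
  neighbor-joining tree on K80 distances over the functional alleles,
  overridable by any Newick input. LRT statistics are far less sensitive to
  the topology than absolute lnL values, which is why absolute lnL from
  other programs is not expected to reproduce (different tree, frequency
  handling and optimizer paths), while 2ΔlnL comparisons are.
* **Branch lengths.** The default optimizes κ, the class parameters and a
  single tree-scale multiplier on the input branch lengths
  (`branches = "scale"`); `branches = "all"` adds every branch to the
  optimization. For small sets of short, closely related sequences the
  scale factor captures nearly all branch-length signal in the LRTs at a
  fraction of the optimizer dimension; this is the package's default
  trade-off and is stated here rather than hidden.
* **Optimization.** L-BFGS-B on transformed coordinates (log for κ, scale
  and the beta shapes; logit for proportions and ω₀; softmax for the M2a
  simplex; 1 + exp for ω₂/ωₛ), box constraints κ ∈ [0.1, 20],
  ω ∈ [1e-4, 50], beta shapes ∈ [0.005, 99], multi-start (default 5 seeded
  starts, jittered). Relative convergence `factr = 1e7`. Nested-model
  dominance (lnL(M2a) ≥ lnL(M1a), lnL(M8) ≥ lnL(M7)) and the collapse of
  M2a to M1a at p₂ = 0 are asserted in the tests.

Positively selected sites are reported by naive empirical Bayes (NEB,
posterior at the MLEs, the default) or Bayes empirical Bayes (BEB) over a
10-point grid per class parameter with a uniform prior, holding κ and
branch lengths at their MLEs — the grid scheme of the standard BEB method,
restricted to the class parameters. Sites with no variation across
sequences are never flagged: an invariant site carries no substitution
evidence, and on a fully invariant alignment the flat likelihood leaves the
class weights unidentified, so flagging from weights alone would be an
artifact.

## Trans-species polymorphism

The full Bayesian MCMC treatment usual for publication-grade MHC trees is
deliberately replaced by neighbor joining on K80 distances: the TSP
statements the pipeline makes depend only on topology (which species
interleave), not on posterior support values. The NJ implementation clamps
negative branch lengths to zero, moving the deficit to the sibling branch
so the pair's summed length is preserved, and is verified against `ape::nj`
topologies and against exact recovery of additive matrices. Gamma rate
heterogeneity is omitted by default (no shape estimate is available from a
distance matrix alone); `gamma_alpha` applies the K80+Γ correction when the
user supplies a shape. Columns with gaps or ambiguity codes are excluded
pairwise.

TSP evidence is reported two ways: groups of identical sequences spanning
two or more species (`identical_allele_groups()`, with a trimmed rule that
matches records of different lengths over their shared window — records
from different studies often cover different amplicon spans), and species
that fail the monophyly test on the unrooted tree (a species is
monophyletic iff some bipartition separates exactly its tips). The
monophyly test is verified against a rooted-clade oracle on random trees.
The trimming rule here is overlap-based (exact substring), not
conservation-based column filtering; records that overlap but with
mismatches do not group.

## The synthetic cohort generator

The generator emulates the study conditions and is the ground-truth source
for every recovery test:

* **Allele pool**: 11 functional alleles and 3 pseudogenes over 80 codons
  plus a 2-nt frame offset. Alleles descend from a random stop-free root on
  a star phylogeny with K80-weighted substitutions (κ = 2) and
  stop-avoidance resampling, calibrated so the mean pairwise p-distance
  hits a target (default 0.20 — MHC exon 2 alleles from multiple paralogs
  are highly diverged). Each pseudogene is a functional allele with exactly
  one base deleted (germline, not an artifact).
* **Genotypes**: two haplotypes per locus per individual, drawn from
  per-subpopulation haplotype frequency tables; 19 eastern, 11 northern, 2
  admixed. A linked allele pair is modelled as a joint haplotype, so it
  co-occurs perfectly. A null haplotype lets carrier counts vary; draws are
  rejected until each individual carries at least one functional allele.
* **Clones**: counts per individual are Poisson(26.9) with a minimum of one
  (the data report only a mean; Poisson is an assumption, stated as such).
  Chimeras (per-clone probability, default 0.02) join two distinct parental
  alleles of the same individual at a uniform crossover point — the
  simplest single-switch template-switching model; a chimera requested for
  a single-allele individual is downgraded to faithful and logged. Point
  errors are uniform base substitutions (default 0.001/base); indel errors
  are not simulated. Defaults reflect a high-fidelity polymerase on a short
  (242-nt) amplicon, where published chimera rates are in the low percent
  and per-clone point errors are rare.

What the generator does **not** emulate: chromatogram/quality structure,
direction-reconciliation of reads (inputs are assumed direction-matched
upstream), coalescent structure in the allele genealogy, PCR-efficiency
differences between templates, and chimera hotspots. Passing recovery tests
therefore show the *filtering logic* is sound under these idealized noise
models, not that any particular wet-lab error profile is handled.

## Numerical and degenerate-input choices

* Fisher p-values use a 1e-7 relative tolerance when comparing table
  probabilities (floating-point ties), matching R's convention.
* Jukes–Cantor saturation (p ≥ 3/4) yields `NA` with an explicit
  `undefined` flag; ω is reported only when dS > 0.
* K80 saturation (non-positive log argument) flags the pair infinite;
  `neighbor_joining()` refuses non-finite matrices.
* Zero-length branches are clamped to 1e-8 before fitting; transition
  matrices at t ≤ 1e-12 are the identity.
* Allele-naming ties break by first observation, making names reproducible
  across runs; the pipeline report embeds the package version, seed and a
  config fingerprint.
* All simulation sizes in the tests (8-taxon trees, 65–100 codons, 20
  replicates for power/size/recovery, 200 replicates for divergence
  calibration) were chosen as the smallest designs in which the respective
  effects are comfortably detectable.

## Limitations

* The two-detection rule cannot exclude artifacts that arise twice
  independently: a chimera recurring from the same parent pair, or — the
  numerically dominant mode at moderate error rates — the *same* point
  error hitting two clones of a high-copy allele. With ~860 clones and a
  per-base error rate of 1e-3, the expected number of such duplicated
  error variants is of order one per cohort, so "zero false alleles" is
  not a property this filter can guarantee; it only becomes effectively
  safe when per-clone errors are rare (roughly below a few per hundred
  thousand bases, as for the highest-fidelity polymerases). The recovery
  tests report false-call counts rather than assuming them away, and real
  studies cross-check validated alleles against external databases (out of
  scope here).
* Positively selected sites are *reported* by the pipeline only when the
  corresponding positive-selection model beats its null in the LRT. This
  mirrors standard practice, and has a technical reason: without LRT
  support the M2a fit can sit on the ridge where the "positive" class has
  ω₂ ≈ 1 and a large weight — it then duplicates the neutral class, and
  class-membership posteriors say nothing about selection.
  `identify_selected_sites()` itself stays a pure posterior threshold on
  the fit it is given.
* ω from NG86 counting is estimator-variant sensitive at the ±0.05 level;
  the ABS/overall/non-ABS *ordering* is the robust statement.
* Absolute site-model lnL values depend on tree, frequency model and
  optimizer path; only likelihood-ratio statistics and the identity of
  flagged sites should be compared across implementations.
* BEB here integrates over the class parameters only (10-point grids),
  holding κ and branch lengths at their MLEs.
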