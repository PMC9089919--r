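Package: drbdiv
Title: Clone-Based MHC Class II DRB Genotyping and Selection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying major histocompatibility complex (MHC)
    class II DRB exon 2 diversity from clone-based amplicon sequencing of a
    wild mustelid population. Collapses plasmid clone sequences into validated
    alleles, classifies functional alleles versus frameshift pseudogenes,
    builds individual-by-allele genotype matrices and compares regional
    subpopulations (Fisher exact and Welch tests), estimates dN/dS with
    Nei-Gojobori counting partitioned into antigen-binding and non-binding
    codons, fits codon site models (M0, M1a, M2a, M7, M8) with likelihood
    ratio tests and empirical-Bayes identification of positively selected
    sites, and tests for trans-species polymorphism with K80 distances,
    neighbor joining and species-monophyly checks. A synthetic-data module
    generates allele pools, two-subpopulation genotypes and clone sets with
    PCR point errors and single-crossover chimeras, with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Matrix,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
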