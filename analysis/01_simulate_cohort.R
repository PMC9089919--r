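#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort -- an allele pool of 11
# functional alleles and 3 one-base-deletion pseudogenes over the 242-nt
# amplicon, multi-locus genotypes for 19 eastern, 11 northern and 2 admixed
# individuals (with a perfectly linked allele pair), and ~26.9 plasmid
# clones per individual carrying PCR point errors and chimeras.

suppressMessages(library(drbdiv))
dir.create("results", showWarnings = FALSE)
seed <- 20260920L

sim <- simulate_wolverine_cohort(seed = seed)
labels <- stats::setNames(sim$truth$individuals$subpop,
                          sim$truth$individuals$individual_id)

write_clone_fasta(sim$clones, "results/clones.fasta")
write_truth_tsv(sim$truth, "results/truth.tsv")
write_provenance_tsv(sim$clones, "results/provenance.tsv")
write_labels(labels, "results/labels.tsv")
write_fasta(c(sim$pool$functional, sim$pool$pseudogene),
            "results/true_alleles.fasta")

prov <- table(sim$clones$provenance)
message("cohort: ", nrow(sim$truth$individuals), " individuals, ",
        nrow(sim$clones), " clones (",
        paste(names(prov), prov, sep = "=", collapse = ", "), ")")
message("allele pool: ", length(sim$pool$functional), " functional + ",
        length(sim$pool$pseudogene), " pseudogenes; mean pairwise p-distance ",
        round(pool_mean_p_distance(sim$pool), 3))
message("wrote results/clones.fasta, truth.tsv, provenance.tsv, labels.tsv")
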