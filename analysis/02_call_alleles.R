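#!/usr/bin/env Rscript
# Stage 2: collapse the clone library to candidate sequences, validate with
# the two-detection rule, classify open reading frames, and assemble the
# genotype matrix. Compares the recovered catalog against the simulated
# ground truth written by stage 1.

suppressMessages(library(drbdiv))

clones <- read_clone_fasta("results/clones.fasta")
labels <- read_labels("results/labels.tsv")
res <- call_alleles(clones, labels)

write_fasta(res$alleles, "results/alleles.fasta")
write_genotype_tsv(res$genotypes, "results/genotypes.tsv")

st <- attr(res$alleles, "status")
message("validated: ", sum(st == "functional"), " functional alleles, ",
        sum(st == "pseudogene"), " pseudogenes; rejected ",
        length(res$rejected_singletons), " singleton sequences")

truth <- read_fasta("results/true_alleles.fasta")
recovered <- sum(res$alleles %in% truth)
false_fn <- sum(!res$alleles[st == "functional"] %in% truth)
message("of the validated alleles, ", recovered, "/", length(res$alleles),
        " match a true allele; false functional alleles: ", false_fn)
message("wrote results/alleles.fasta, genotypes.tsv")
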