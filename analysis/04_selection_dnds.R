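#!/usr/bin/env Rscript
# Stage 4: Nei-Gojobori dN/dS on the validated functional alleles,
# partitioned into antigen-binding (ABS) and non-ABS codons, with
# codon-bootstrap standard errors.

suppressMessages(library(drbdiv))

alleles <- read_fasta("results/alleles.fasta")
# functional alleles only: full-length, stop-free amplicons
keep <- vapply(alleles, function(s) classify_sequence(s)$status, "") == "functional"
inframe <- vapply(alleles[keep], function(s) {
  paste0(inframe_codons(s, 2), collapse = "")
}, character(1))

mask <- load_abs_mask()
rates <- partitioned_rates(inframe, mask, bootstrap_reps = 1000, seed = 1)
utils::write.table(rates, "results/dnds.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

for (i in seq_len(nrow(rates))) {
  message(sprintf("%-8s %2d codons: dN = %.3f +/- %.3f, dS = %.3f +/- %.3f, omega = %s",
                  rates$partition[i], rates$n_codons[i], rates$dN[i],
                  rates$dN_se[i], rates$dS[i], rates$dS_se[i],
                  ifelse(is.na(rates$omega[i]), "undefined",
                         sprintf("%.3f", rates$omega[i]))))
}
message("wrote results/dnds.tsv")
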