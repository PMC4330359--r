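#!/usr/bin/env Rscript

# NMR chemical-shift-perturbation mapping on synthetic titration data: a
# 79-residue DNA-binding domain observed free and DNA-bound, with ten
# residues planted above the 0.1 ppm large-perturbation line.

suppressPackageStartupMessages(library(tfcoop))
dir.create("results", showWarnings = FALSE)

planted <- data.frame(
  residue_index = c(4, 16, 20, 24, 25, 34, 42, 43, 56, 65),
  delta_h = c(0.15, 0.12, 0.20, 0.11, 0.13, 0.18, 0.25, 0.14, 0.12, 0.16),
  delta_n = c(0.8, 0.5, 1.2, 0.4, 0.6, 1.0, 1.5, 0.7, 0.5, 0.9)
)
sim <- simulate_peak_lists(79, perturbed = planted, jitter_sd = 1e-4, seed = 11)
write.table(sim$state_a, "results/peaks_free.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$state_b, "results/peaks_bound.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

csp <- compare_states(read_peaklist_tsv("results/peaks_free.tsv"),
                      read_peaklist_tsv("results/peaks_bound.tsv"))
write.table(csp, "results/csp_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

hits <- classify_perturbed(csp, threshold = 0.1)
writeLines(as.character(hits), "results/perturbed_residues.txt")

cat(sprintf("residues observed: %d; matched in both states: %d\n",
            nrow(csp), sum(csp$status == "ok")))
cat(sprintf("large perturbations (> 0.1 ppm): %s\n",
            paste(hits, collapse = ", ")))
cat(sprintf("planted set recovered exactly: %s\n",
            identical(as.integer(hits), as.integer(sort(planted$residue_index)))))
cat(sprintf("max weighted CSP: %.3f ppm at residue %d\n",
            max(csp$weighted, na.rm = TRUE),
            csp$residue_index[which.max(csp$weighted)]))
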