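#!/usr/bin/env Rscript

# Dissect the composite-element architecture: verify the annealed duplex,
# locate the composite site, build the spacing series and the
# nucleotide-switch mutant panel, and contrast forward vs flipped pax
# orientation. The half-site boundaries used here are the packaged annotation
# of the native element (figure-derived, see the methods vignette).

suppressPackageStartupMessages(library(tfcoop))
dir.create("results", showWarnings = FALSE)

dc5_f <- "TTCATTGTTGTTGCTCACCTACCATGGATCC"
dc5_r <- "GGATCCATGGTAGGTGAGCAACAACAATGAA"
cat(sprintf("duplex check: %d bp perfect duplex\n", anneal_check(dc5_f, dc5_r)))

motif <- composite_motif("CATTGT", gap = 0, pax_word = "TGTTGC")
hits <- scan_composite(motif, dc5_f, seq_id = "DC5")
cat(sprintf("composite site on the native element: offset %d, strand %s\n",
            hits$offset[1], hits$strand[1]))

# spacing series: insertions on the native zero-spacer element (+1..+5);
# contractions additionally shown on a 3 bp spacer derivative, since a
# zero-spacer junction cannot shrink without eating a half-site
ins <- enumerate_spacer_variants(dc5_f, c(2, 8), c(8, 14), deltas = 1:5,
                                 insert_bases = "ACGTA")
spaced <- paste0(substr(dc5_f, 1, 8), "GCA", substr(dc5_f, 9, nchar(dc5_f)))
del <- enumerate_spacer_variants(spaced, c(2, 8), c(11, 17), deltas = c(-2, -1),
                                 insert_bases = NULL)
spacer_series <- rbind(cbind(template = "DC5", ins),
                       cbind(template = "DC5+3bp", del))
write.table(spacer_series, "results/spacer_series.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("spacing series written: %d variants (deltas %s)\n",
            nrow(spacer_series),
            paste(sort(spacer_series$delta), collapse = ",")))

# nucleotide switches: the synthetic Pax6-like PFM shipped with the package
# identifies the high-information positions deviating from the degenerate
# half-site, and the mutant panel converts them toward the consensus
pfm <- read_pfm(system.file("extdata", "pax6_like_synthetic.pfm",
                            package = "tfcoop"))
halfsite <- "GCAATCAAATCAGT"
sw <- high_ic_deviations(pfm, halfsite, ic_threshold = 1, pseudocount = 0)
cat(sprintf("switch positions (IC >= 1 bit, deviating): %s\n",
            paste(sw, collapse = ", ")))

consensus <- paste(pfm_consensus(pfm), collapse = "")
mutants <- enumerate_switch_mutants(halfsite, consensus, sw, max_order = 3)
write.table(mutants, "results/switch_mutants.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("switch-mutant panel: %d variants up to order 3 (%s ...)\n",
            nrow(mutants), paste(head(mutants$label, 6), collapse = ", ")))

# flipped pax orientation: the native element carries no flipped-consensus
# composite, while a constructed flipped element is found only in flipped mode
flipped <- build_flipped_composite(motif)
cat(sprintf("flipped-orientation scan of the native element: %d hits\n",
            nrow(scan_composite(flipped, dc5_f))))
flip_elem <- paste0("GCA", "CATTGT", reverse_complement("TGTTGC"), "GCATT")
cat(sprintf("constructed flipped element: forward-mode %d hits, flipped-mode %d hits\n",
            nrow(scan_composite(motif, flip_elem, both_strands = FALSE)),
            nrow(scan_composite(flipped, flip_elem, both_strands = FALSE))))
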