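#!/usr/bin/env Rscript

# Co-binding analysis on synthetic ChIP-seq data: intersect two factors'
# peak sets into co-bound regions, then measure what fraction of the
# co-bound regions contain (i) the composite sox word and (ii) a consensus
# pax word. The synthetic genome plants the sox composite in ~30% of regions
# and the pax consensus in ~3%, emulating the regime where co-bound
# enhancers carry sox motifs far more often than pax consensus motifs.

suppressPackageStartupMessages(library(tfcoop))
dir.create("results", showWarnings = FALSE)
set.seed(91)

# two peak sets over one synthetic chromosome: factor B peaks offset within
# factor A peaks so that every pair overlaps into one co-bound region
n_regions <- 100
region_w <- 200
gap_bp <- 400
a_start <- (0:(n_regions - 1)) * (region_w + gap_bp)
pax_peaks <- peak_set(rep("chr1", n_regions), a_start, a_start + region_w,
                      label = "PAX")
sox_peaks <- peak_set(rep("chr1", n_regions), a_start + 50,
                      a_start + region_w + 50, label = "SOX")
write_bed(pax_peaks, "results/pax_peaks.bed")
write_bed(sox_peaks, "results/sox_peaks.bed")

cobound <- intersect_peaks(pax_peaks, sox_peaks, min_overlap = 1)
cobound$name <- sprintf("region%03d", seq_along(cobound))
write_bed(cobound, "results/cobound_regions.bed")
cat(sprintf("co-bound regions: %d (intersection spans of %d x %d peaks)\n",
            length(cobound), length(pax_peaks), length(sox_peaks)))

# region sequences: composite sox motif planted in 30 regions, a consensus
# pax word planted in 3 of the remaining ones
sox_motif <- dc5_like_motif()
with_sox <- plant_composite_motifs(150, 30, sox_motif,
                                   sites_per_sequence = 1, seed = 92)
without <- plant_composite_motifs(150, 70, sox_motif,
                                  sites_per_sequence = 0, seed = 93)
seqs <- c(with_sox$sequences, without$sequences)
names(seqs) <- cobound$name
pax_word <- "TTCACGCATG"
for (i in 71:73) {  # plant the pax consensus word in 3 regions without sox sites
  s <- seqs[[i]]
  seqs[[i]] <- paste0(substr(s, 1, 40), pax_word,
                      substr(s, 41 + nchar(pax_word), nchar(s)))
}
write_fasta(seqs, "results/cobound_regions.fa")

res_sox <- region_motif_fraction(cobound, seqs, sox_motif)
res_pax <- region_motif_fraction(cobound, seqs, pax_word)
report <- data.frame(
  motif = c("composite sox word", "pax consensus word"),
  n_regions = c(res_sox$n_regions, res_pax$n_regions),
  n_with_hit = c(res_sox$n_with_hit, res_pax$n_with_hit),
  fraction = c(res_sox$fraction, res_pax$fraction)
)
write.table(report, "results/cobinding_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("composite sox word: %d/%d regions (%.0f%%)\n",
            res_sox$n_with_hit, res_sox$n_regions, 100 * res_sox$fraction))
cat(sprintf("pax consensus word: %d/%d regions (%.0f%%)\n",
            res_pax$n_with_hit, res_pax$n_regions, 100 * res_pax$fraction))
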