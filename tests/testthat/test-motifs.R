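DC5_F <- "TTCATTGTTGTTGCTCACCTACCATGGATCC"
DC5_R <- "GGATCCATGGTAGGTGAGCAACAACAATGAA"

test_that("reverse complement is IUPAC-aware and involutive", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement(DC5_F), DC5_R)
  expect_equal(reverse_complement("RYSWKM"), "KMWSRY")
  expect_error(reverse_complement("ACXGT"), "invalid IUPAC letter 'X' at position 3")

  set.seed(11)
  letters15 <- c("A","C","G","T","R","Y","S","W","K","M","B","D","H","V","N")
  for (i in 1:25) {
    x <- random_dna(sample(5:40, 1), alphabet = letters15)
    expect_equal(reverse_complement(reverse_complement(x)), x)
  }
})

test_that("annealing check verifies perfect duplexes and locates mismatches", {
  expect_equal(anneal_check(DC5_F, DC5_R), 31L)
  expect_equal(anneal_check("AC", "GT"), 2L)
  expect_error(anneal_check("AC", "GG"), "position 1")
  expect_error(anneal_check("ACG", "GT"), "length mismatch")
})

test_that("degenerate word matching follows IUPAC classes", {
  expect_true(match_word("N", "A", 0))
  expect_true(match_word("N", "T", 0))
  expect_true(match_word("CATTGT", DC5_F, 2))
  expect_false(match_word("CATTGT", DC5_F, 3))
  expect_true(match_word("catTGT", tolower(DC5_F), 2))  # case-insensitive
  expect_error(match_word("CATTGT", "ACG", 0), "exceeds sequence length")
  expect_error(iupac_word("AXG"), "invalid IUPAC")
})

test_that("composite scan finds the native element exactly once", {
  m <- composite_motif("CATTGT", gap = 0, pax_word = "TGTTGC")
  expect_equal(nrow(scan_composite(m, "ACGT")), 0L)  # shorter than the motif

  hits <- scan_composite(m, DC5_F, both_strands = TRUE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 2L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$end - hits$start, motif_span(m))
})

test_that("composite scan agrees with the exhaustive character-level oracle", {
  set.seed(23)
  words <- c("CATTGT", "CWTTGT", "TGTTGY", "ASGT", "NNAC", "RYK")
  n_cases <- 1000
  for (i in seq_len(n_cases)) {
    m <- composite_motif(sample(words, 1), gap = sample(0:3, 1),
                         pax_word = sample(words, 1),
                         pax_orientation = sample(c("forward", "flipped"), 1))
    seq <- random_dna(sample(15:45, 1))
    got <- scan_composite(m, seq, both_strands = TRUE)
    want <- oracle_scan(m, seq)
    expect_equal(got[c("strand", "start", "end")],
                 want[c("strand", "start", "end")],
                 ignore_attr = TRUE)
  }
})

test_that("hits mirror under reverse complement with strands swapped", {
  m <- composite_motif("CATTG", gap = 1, pax_word = "TGTWG")
  for (i in 1:50) {
    seq <- plant_composite_motifs(80, 1, m, sites_per_sequence = 2,
                                  seed = i)$sequences[[1]]
    fwd <- scan_composite(m, seq)
    expect_gte(nrow(fwd), 2L)
    rev <- scan_composite(m, reverse_complement(seq))
    n <- nchar(seq)
    mirrored <- data.frame(start = n - rev$end, end = n - rev$start,
                           strand = as.character(ifelse(rev$strand == "+", "-", "+")))
    mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
    expect_equal(fwd[c("start", "end", "strand")], mirrored,
                 ignore_attr = TRUE)
  }
})

test_that("soft-masked bases match by default and are excluded on request", {
  m <- composite_motif("CATTGT", 0, "TGTTGC")
  soft <- paste0(substr(DC5_F, 1, 2), tolower(substr(DC5_F, 3, 8)),
                 substr(DC5_F, 9, nchar(DC5_F)))
  expect_equal(nrow(scan_composite(m, soft)), 1L)
  expect_equal(nrow(scan_composite(m, soft, respect_mask = TRUE)), 0L)
})

test_that("flipping the pax orientation is involutive and changes scan semantics", {
  m <- composite_motif("CATTGT", 0, "TGTTGC")
  expect_equal(build_flipped_composite(build_flipped_composite(m)), m)

  # a sequence carrying sox + revcomp(pax) is found only by the flipped motif
  seq_flip <- paste0("AAA", "CATTGT", reverse_complement("TGTTGC"), "AAA")
  expect_equal(nrow(scan_composite(build_flipped_composite(m), seq_flip,
                                   both_strands = FALSE)), 1L)
  expect_equal(nrow(scan_composite(m, seq_flip, both_strands = FALSE)), 0L)

  # flipped scan finds nothing on unmodified forward sites (pax word
  # non-palindromic)
  planted <- plant_composite_motifs(200, 5, m, sites_per_sequence = 2, seed = 13)
  flipped_hits <- scan_composite_set(build_flipped_composite(m),
                                     planted$sequences)
  expect_equal(nrow(flipped_hits), 0L)
})

test_that("spacer variants insert and delete at the junction, preserving half-sites", {
  template <- DC5_F

  # a zero-spacer element cannot shrink further: deletions must be refused
  expect_error(enumerate_spacer_variants(template, c(2, 8), c(8, 14), -1,
                                         insert_bases = "A"),
               "half-site")

  # the full -2..+5 spacing series on a template carrying a 3 bp spacer
  spaced <- paste0(substr(template, 1, 8), "GCA", substr(template, 9, 31))
  deltas <- setdiff(-2:5, 0)
  out <- enumerate_spacer_variants(spaced, c(2, 8), c(11, 17), deltas,
                                   insert_bases = "AAAAA")
  expect_equal(nrow(out), 7L)
  expect_equal(nchar(out$sequence), nchar(spaced) + out$delta)

  # both half-sites survive every delta verbatim
  out2 <- enumerate_spacer_variants(spaced, c(2, 8), c(11, 17),
                                    deltas = -2:5, insert_bases = "TTTTT")
  for (k in seq_len(nrow(out2))) {
    s <- out2$sequence[k]
    expect_equal(substr(s, 3, 8), "CATTGT")
    expect_equal(substr(s, 12 + out2$delta[k], 17 + out2$delta[k]), "TGTTGC")
  }
  expect_equal(out2$sequence[out2$delta == 0], spaced)

  expect_error(enumerate_spacer_variants(spaced, c(2, 8), c(11, 17), 2),
               "insert_bases")
})

test_that("switch mutants enumerate labelled subsets toward the consensus", {
  wild <- "GCAATCAAATCAGT"
  cons <- "GCTATCAGCTTAGT"  # differs at 1-based positions 3, 8, 9, 11
  out <- enumerate_switch_mutants(wild, cons, c(3, 8, 9, 11), max_order = 3)
  expect_equal(nrow(out), 14L)  # 4 + 6 + 4
  expect_equal(sum(out$order == 1), 4L)

  singles <- enumerate_switch_mutants(wild, cons, c(3, 8, 9, 11), max_order = 1)
  expect_equal(nrow(singles), 4L)
  expect_setequal(singles$label, c("T3", "G8", "C9", "T11"))

  double <- out[out$label == "G8C9", ]
  expect_equal(nrow(double), 1L)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(ham(double$sequence, wild), 2L)
  expect_equal(ham(double$sequence, cons), ham(wild, cons) - 2L)

  expect_warning(enumerate_switch_mutants("AAAA", "AAAT", c(1, 4)),
                 "agree at position")
})
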