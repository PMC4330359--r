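# Independent oracles used to cross-check the package implementations.
# Each takes a deliberately different computational route from the code under
# test: multivariate Newton root finding (pracma) for the equilibrium solver,
# character-level position-by-position matching for the composite scanner,
# and quadratic all-pairs interval arithmetic for peak intersection.

# --- equilibrium: Newton solve of the three mass balances in log space ------

oracle_equilibrium <- function(params, totals) {
  ks <- params$kd_sox; kp <- params$kd_pax; w <- params$omega
  f <- function(u) {
    s <- exp(u[1]); p <- exp(u[2]); d <- exp(u[3])
    sd <- s * d / ks; pd <- p * d / kp; spd <- w * s * p * d / (ks * kp)
    c(d + sd + pd + spd - totals$dna_tot,
      s + sd + spd - totals$sox_tot,
      p + pd + spd - totals$pax_tot)
  }
  u0 <- log(c(totals$sox_tot, totals$pax_tot, totals$dna_tot) / 2)
  sol <- pracma::fsolve(f, u0, tol = 1e-13)
  s <- exp(sol$x[1]); p <- exp(sol$x[2]); d <- exp(sol$x[3])
  c(f_free = d / totals$dna_tot,
    f_sox = s * d / ks / totals$dna_tot,
    f_pax = p * d / kp / totals$dna_tot,
    f_dimer = w * s * p * d / (ks * kp) / totals$dna_tot)
}

# --- composite scanning: character-level exhaustive scan --------------------

iupac_class <- function(letter) strsplit(Biostrings::IUPAC_CODE_MAP[[toupper(letter)]], "")[[1]]

oracle_match_at <- function(pattern, seq, start0) {
  pat <- strsplit(toupper(pattern), "")[[1]]
  sub <- strsplit(toupper(substr(seq, start0 + 1, start0 + length(pat))), "")[[1]]
  if (length(sub) < length(pat)) return(FALSE)
  all(mapply(function(w, b) b %in% iupac_class(w), pat, sub))
}

# full-motif pattern; minus-strand hits found by matching the reverse
# complement of the pattern against the forward sequence
oracle_scan <- function(motif, seq, seq_id = "seq") {
  pax_eff <- if (motif$pax_orientation == "flipped") {
    tfcoop::reverse_complement(as.character(motif$pax_word))
  } else {
    as.character(motif$pax_word)
  }
  pattern <- paste0(as.character(motif$sox_word),
                    strrep("N", motif$gap), pax_eff)
  rc_pattern <- tfcoop::reverse_complement(pattern)
  span <- nchar(pattern)
  n <- nchar(seq)
  rows <- list()
  if (n >= span) {
    for (start0 in 0:(n - span)) {
      if (oracle_match_at(pattern, seq, start0)) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = seq_id, strand = "+", start = start0, end = start0 + span,
          stringsAsFactors = FALSE)
      }
      if (oracle_match_at(rc_pattern, seq, start0)) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = seq_id, strand = "-", start = start0, end = start0 + span,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(0), strand = character(0),
               start = integer(0), end = integer(0))
  out[order(out$start, out$strand), , drop = FALSE]
}

# --- peak intersection: quadratic all-pairs with sweep merge ----------------

# a, b: data.frames with chrom, start, end (0-based half-open)
oracle_intersect <- function(a, b, min_overlap = 1L) {
  spans <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      s <- max(a$start[i], b$start[j])
      e <- min(a$end[i], b$end[j])
      if (e - s >= min_overlap) {
        spans[[length(spans) + 1L]] <- c(s, e, i)
      }
    }
  }
  if (length(spans) == 0) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  }
  df <- data.frame(
    chrom = a$chrom[vapply(spans, `[`, numeric(1), 3)],
    start = vapply(spans, `[`, numeric(1), 1),
    end = vapply(spans, `[`, numeric(1), 2))
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  merged <- df[1, , drop = FALSE]
  if (nrow(df) > 1) {
    for (k in 2:nrow(df)) {
      last <- nrow(merged)
      if (df$chrom[k] == merged$chrom[last] && df$start[k] <= merged$end[last]) {
        merged$end[last] <- max(merged$end[last], df$end[k])
      } else {
        merged <- rbind(merged, df[k, ])
      }
    }
  }
  rownames(merged) <- NULL
  merged
}

granges_to_bed_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# lane -> omega convenience used across tests
omega_from_lanes <- function(lanes, epsilon = 0.01) {
  lapply(seq_len(nrow(lanes)), function(i) {
    estimate_omega(normalize_lane(lanes$i_free[i], lanes$i_sox[i],
                                  lanes$i_pax[i], lanes$i_dimer[i]),
                   epsilon = epsilon)
  })
}
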