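# Synthetic-data generators. Everything is deterministic under a fixed seed;
# each generator returns its ground truth alongside the data.

#' Registry of named element presets
#'
#' Binding-parameter presets for the elements studied by quantitative EMSA,
#' calibrated to the printed cooperativity regimes: strongly cooperative
#' native elements (DC5 omega = 25, N3 omega = 50), additive consensus
#' element (DC5con omega = 1), competitive element with a weak pax half-site
#' whose ternary band stays below detectability (LE9 omega = 0.2), expanded
#' spacers with collapsed cooperativity (+1..+5, omega = 2) and contracted
#' spacers with competitive binding (-1/-2, omega = 0.3). The absolute Kd
#' magnitudes are package choices in the 100--1000 nM range (no absolute Kd
#' values are published for these elements) and every preset's `note` says so.
#'
#' @return Named list of `element_preset` objects, each holding
#'   [binding_params()] plus a provenance `note`.
#' @examples
#' preset_registry()[["DC5"]]$params$omega  # 25
#' @export
preset_registry <- function() {
  mk <- function(name, kd_sox, kd_pax, omega, note) {
    structure(list(name = name,
                   params = binding_params(kd_sox, kd_pax, omega, label = name),
                   note = note),
              class = "element_preset")
  }
  kd_note <- "Kd magnitudes are package-chosen (not published values)"
  presets <- list(
    mk("DC5",    100, 1000, 25,
       paste("native element, cooperative; degenerate low-affinity pax half-site;", kd_note)),
    mk("N3",     100, 1000, 50,
       paste("native element, strongly cooperative;", kd_note)),
    mk("DC5con", 100,  100, 1,
       paste("consensus pax half-site, additive binding;", kd_note)),
    mk("LE9",    100, 8000, 0.2,
       paste("competitive; very weak pax site keeps the ternary band sub-threshold;", kd_note)),
    mk("spacer-2", 100, 1000, 0.3,
       paste("2 bp spacer contraction, competitive;", kd_note)),
    mk("spacer-1", 100, 1000, 0.3,
       paste("1 bp spacer contraction, competitive;", kd_note)),
    mk("spacer+1", 100, 1000, 2,
       paste("1 bp spacer expansion, cooperativity collapsed;", kd_note)),
    mk("spacer+2", 100, 1000, 2,
       paste("2 bp spacer expansion, cooperativity collapsed;", kd_note)),
    mk("spacer+3", 100, 1000, 2,
       paste("3 bp spacer expansion, cooperativity collapsed;", kd_note)),
    mk("spacer+4", 100, 1000, 2,
       paste("4 bp spacer expansion, residual weak cooperativity;", kd_note)),
    mk("spacer+5", 100, 1000, 2,
       paste("5 bp spacer expansion, cooperativity collapsed;", kd_note))
  )
  names(presets) <- vapply(presets, `[[`, character(1), "name")
  presets
}

#' Look up one element preset by name
#' @param name Preset name, e.g. `"DC5"`.
#' @return An `element_preset`.
#' @export
get_preset <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg)) {
    stop("unknown element preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}

#' Simulate replicate gel-lane quantifications
#'
#' Draws noisy four-band lane quantifications from the equilibrium model:
#' each replicate solves the noise-free equilibrium, then multiplies each
#' band's fraction by an independent median-1 lognormal factor with
#' coefficient of variation `noise_cv` (densitometry error is proportional to
#' intensity). Because the cooperativity statistic is a ratio of the four
#' bands, the median-1 noise leaves its median centred on the true omega.
#'
#' @param params A [binding_params()].
#' @param totals A [species_totals()].
#' @param n_replicates Number of lanes (>= 1).
#' @param noise_cv Coefficient of variation of the multiplicative band noise
#'   (>= 0; default 0.1).
#' @param seed Integer seed; identical seed + config gives identical lanes.
#' @param element Element name recorded in the lane table (defaults to the
#'   params label).
#' @return data.frame with columns `lane_id`, `element`, `replicate`,
#'   `i_free`, `i_sox`, `i_pax`, `i_dimer`; attribute `truth` holds the
#'   noise-free fractions and the true omega.
#' @export
simulate_gel_replicates <- function(params, totals, n_replicates = 10L,
                                    noise_cv = 0.1, seed = 1L,
                                    element = params$label) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  fr <- solve_equilibrium(params, totals)
  sdlog <- sqrt(log(1 + noise_cv^2))
  set.seed(as.integer(seed))
  lanes <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    noise <- if (noise_cv == 0) rep(1, 4) else exp(stats::rnorm(4, 0, sdlog))
    data.frame(
      lane_id = sprintf("%s_rep%02d", if (nzchar(element)) element else "lane", r),
      element = element,
      replicate = r,
      i_free  = fr[["f_free"]]  * noise[1],
      i_sox   = fr[["f_sox"]]   * noise[2],
      i_pax   = fr[["f_pax"]]   * noise[3],
      i_dimer = fr[["f_dimer"]] * noise[4],
      stringsAsFactors = FALSE
    )
  }))
  attr(lanes, "truth") <- list(fractions = fr, omega_true = params$omega,
                               params = params, totals = totals,
                               noise_cv = noise_cv, seed = as.integer(seed))
  lanes
}

# sample one concrete realisation of a degenerate word
.realize_word <- function(word) {
  classes <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(toupper(word), "")[[1]]], "")
  paste(vapply(classes, function(b) b[sample.int(length(b), 1L)], character(1)),
        collapse = "")
}

#' Generate sequences with planted composite motifs and full ground truth
#'
#' Builds `n_sequences` random uniform-composition sequences and plants
#' non-overlapping composite-motif instances (concrete realisations of the
#' degenerate words, random strand) at random positions. After planting, the
#' sequences are exhaustively re-scanned and any accidental background match
#' outside the planted sites is destroyed by point mutation, so the returned
#' truth table and an exhaustive scan agree exactly.
#'
#' @param genome_length Length of each sequence (bp).
#' @param n_sequences Number of sequences.
#' @param motif A [composite_motif()].
#' @param sites_per_sequence Planted instances per sequence (may be 0).
#' @param seed Integer seed.
#' @param gc Background GC content (default 0.5, uniform composition).
#' @param max_fix_rounds Rounds of accidental-match correction before giving
#'   up (default 25).
#' @return List with `sequences` (named character vector) and `truth`
#'   (data.frame `seq_id`, `offset`, `strand`, `start`, `end` as in
#'   [scan_composite()]).
#' @export
plant_composite_motifs <- function(genome_length, n_sequences, motif,
                                   sites_per_sequence, seed = 1L, gc = 0.5,
                                   max_fix_rounds = 25L) {
  stopifnot(inherits(motif, "composite_motif"))
  span <- motif_span(motif)
  if (span > genome_length) stop("motif does not fit in genome_length")
  set.seed(as.integer(seed))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  pax_eff <- if (motif$pax_orientation == "flipped") {
    reverse_complement(as.character(motif$pax_word))
  } else {
    as.character(motif$pax_word)
  }

  seqs <- character(n_sequences)
  names(seqs) <- sprintf("seq%03d", seq_len(n_sequences))
  truth <- list()
  for (i in seq_len(n_sequences)) {
    chars <- sample(names(probs), genome_length, replace = TRUE, prob = probs)
    placed <- integer(0)  # planted span starts (0-based)
    if (sites_per_sequence > 0) {
      tries <- 0L
      while (length(placed) < sites_per_sequence) {
        tries <- tries + 1L
        if (tries > 1000L) {
          stop("cannot place requested sites without overlap; reduce sites_per_sequence")
        }
        start <- sample.int(genome_length - span + 1L, 1L) - 1L  # 0-based
        if (any(abs(start - placed) < span)) next
        strand <- sample(c("+", "-"), 1L)
        inst_gap <- if (motif$gap > 0) {
          paste(sample(names(probs), motif$gap, replace = TRUE, prob = probs),
                collapse = "")
        } else ""
        inst <- paste0(.realize_word(as.character(motif$sox_word)), inst_gap,
                       .realize_word(pax_eff))
        if (strand == "-") inst <- reverse_complement(inst)
        chars[(start + 1L):(start + span)] <- strsplit(inst, "")[[1]]
        placed <- c(placed, start)
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = names(seqs)[i], strand = strand,
          start = start, end = start + span, stringsAsFactors = FALSE)
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(seq_id = character(0), strand = character(0),
               start = integer(0), end = integer(0))

  # post-correction: mutate away accidental matches not in the truth table
  key <- function(df) paste(df$seq_id, df$start, df$strand)
  for (round in seq_len(max_fix_rounds)) {
    hits <- scan_composite_set(motif, seqs, both_strands = TRUE)
    extra <- hits[!(key(hits) %in% key(truth)), , drop = FALSE]
    if (nrow(extra) == 0) break
    for (j in seq_len(nrow(extra))) {
      id <- extra$seq_id[j]
      # pick a position of the accidental span not inside any planted span
      cand <- (extra$start[j] + 1L):(extra$end[j])  # 1-based positions
      planted <- truth[truth$seq_id == id, , drop = FALSE]
      if (nrow(planted)) {
        inside <- unlist(mapply(function(s, e) (s + 1L):e,
                                planted$start, planted$end, SIMPLIFY = FALSE))
        cand <- setdiff(cand, inside)
      }
      if (length(cand) == 0) next  # overlaps planted sites entirely; leave it
      pos <- cand[sample.int(length(cand), 1L)]
      cur <- substr(seqs[[id]], pos, pos)
      repl <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      substr(seqs[[id]], pos, pos) <- repl
    }
  }
  hits <- scan_composite_set(motif, seqs, both_strands = TRUE)
  extra <- hits[!(key(hits) %in% key(truth)), , drop = FALSE]
  if (nrow(extra) > 0) {
    stop("failed to remove accidental matches after post-correction rounds")
  }
  # planted instances are genuine matches by construction; re-derive offsets
  truth <- hits[order(hits$seq_id, hits$start, hits$strand), , drop = FALSE]
  rownames(truth) <- NULL
  list(sequences = seqs, truth = truth)
}

#' Simulate a pair of NMR peak lists with known perturbations
#'
#' State A amide positions are drawn from realistic ranges (1H 6--10 ppm,
#' 15N 100--135 ppm); state B adds the specified per-residue shift changes
#' plus Gaussian jitter on every peak.
#'
#' @param n_residues Number of residues (indices 1..n).
#' @param perturbed Named list or data.frame mapping residue index to
#'   `c(delta_h, delta_n)`; for a data.frame use columns `residue_index`,
#'   `delta_h`, `delta_n`. May be empty.
#' @param jitter_sd Gaussian jitter SD (ppm) applied independently to state-B
#'   1H and (scaled by 10) 15N coordinates.
#' @param seed Integer seed.
#' @return List with `state_a`, `state_b` (peak-list data.frames) and `truth`
#'   (data.frame `residue_index`, `delta_h`, `delta_n`, `weighted`).
#' @export
simulate_peak_lists <- function(n_residues, perturbed = NULL, jitter_sd = 0,
                                seed = 1L) {
  set.seed(as.integer(seed))
  if (is.null(perturbed)) {
    pert <- data.frame(residue_index = integer(0), delta_h = numeric(0),
                       delta_n = numeric(0))
  } else if (is.data.frame(perturbed)) {
    pert <- perturbed[c("residue_index", "delta_h", "delta_n")]
  } else {
    pert <- data.frame(
      residue_index = as.integer(names(perturbed)),
      delta_h = vapply(perturbed, `[`, numeric(1), 1),
      delta_n = vapply(perturbed, `[`, numeric(1), 2))
  }
  if (any(pert$residue_index < 1) || any(pert$residue_index > n_residues)) {
    stop("perturbed residues outside 1..n_residues")
  }
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  idx <- seq_len(n_residues)
  state_a <- data.frame(
    residue_index = idx,
    residue_code = sample(aa, n_residues, replace = TRUE),
    h_ppm = stats::runif(n_residues, 6, 10),
    n_ppm = stats::runif(n_residues, 100, 135),
    stringsAsFactors = FALSE
  )
  dh <- dn <- numeric(n_residues)
  m <- match(pert$residue_index, idx)
  dh[m] <- pert$delta_h
  dn[m] <- pert$delta_n
  state_b <- state_a
  state_b$h_ppm <- state_a$h_ppm + dh + stats::rnorm(n_residues, 0, jitter_sd)
  state_b$n_ppm <- state_a$n_ppm + dn + stats::rnorm(n_residues, 0, 10 * jitter_sd)
  truth <- data.frame(residue_index = idx, delta_h = dh, delta_n = dn,
                      weighted = weighted_csp(dh, dn))
  list(state_a = state_a, state_b = state_b, truth = truth)
}
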