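# IUPAC nucleotide machinery. Each of the 15 ambiguity letters is encoded as a
# 4-bit mask over A/C/G/T; a sequence base matches a word letter iff its bits
# are a subset of the letter's bits. Matching is case-insensitive so that
# soft-masked (lowercase) genome sequence matches by default.

.IUPAC_BITS <- local({
  base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  codes <- Biostrings::IUPAC_CODE_MAP  # e.g. R = "AG", N = "ACGT"
  bits <- vapply(strsplit(codes, ""), function(b) sum(base_bits[b]), numeric(1))
  out <- as.integer(bits)
  names(out) <- names(codes)
  out
})

.seq_to_bits <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(seq), "")[[1]]
  bits <- .IUPAC_BITS[chars]
  if (anyNA(bits)) {
    bad <- which(is.na(bits))[1]
    stop(sprintf("invalid IUPAC letter '%s' at position %d of %s",
                 chars[bad], bad, what))
  }
  unname(bits)
}

#' Validate a degenerate IUPAC word
#'
#' @param letters A single string over the 15-letter IUPAC nucleotide
#'   alphabet (case-insensitive), e.g. `"CATTGT"` or `"YTTTGYY"`.
#' @return The validated word (uppercased), class `iupac_word`.
#' @export
iupac_word <- function(letters) {
  if (!is.character(letters) || length(letters) != 1L || nchar(letters) == 0) {
    stop("an IUPAC word must be a single non-empty string")
  }
  .seq_to_bits(letters, "word")
  structure(toupper(letters), class = "iupac_word")
}

#' IUPAC-aware reverse complement
#'
#' Reverse-complements a nucleotide sequence, mapping ambiguity codes to their
#' complements (R to Y, M to K, etc.). Delegates to Biostrings.
#'
#' @param seq A single nucleotide string (IUPAC letters).
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("CATTGT")
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0) {
    stop("seq must be a single non-empty string")
  }
  .seq_to_bits(seq)  # informative position-level error for invalid letters
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Check that two oligos anneal into a perfect duplex
#'
#' Verifies Watson--Crick complementarity of a forward and reverse oligo as
#' used when annealing synthesized strands into a double-stranded probe:
#' forward position `i` must pair with reverse position `L + 1 - i`.
#'
#' @param forward,reverse Oligo sequences (5'->3', plain ACGT).
#' @return The duplex length in bp if the oligos are perfectly complementary;
#'   otherwise an error reporting the first non-pairing forward position.
#' @examples
#' anneal_check("CATTGT", "ACAATG")  # 6
#' @export
anneal_check <- function(forward, reverse) {
  if (!nzchar(forward) || !nzchar(reverse)) stop("both oligos must be non-empty")
  if (nchar(forward) != nchar(reverse)) {
    stop(sprintf("length mismatch: forward %d bp, reverse %d bp",
                 nchar(forward), nchar(reverse)))
  }
  expect <- reverse_complement(forward)
  got <- toupper(reverse)
  if (got != expect) {
    diff <- which(strsplit(got, "")[[1]] != strsplit(expect, "")[[1]])
    # reverse-oligo position L+1-i pairs with forward position i
    pos <- nchar(forward) + 1L - max(diff)
    stop(sprintf("oligos do not anneal: mismatch at position %d (forward '%s' cannot pair)",
                 pos, substr(toupper(forward), pos, pos)))
  }
  nchar(forward)
}

#' Match a degenerate word at one sequence position
#'
#' @param word An [iupac_word()] (or plain string of IUPAC letters).
#' @param seq Subject nucleotide sequence.
#' @param pos 0-based start position of the attempted match.
#' @return TRUE iff every sequence base lies in the IUPAC class of the
#'   corresponding word letter.
#' @export
match_word <- function(word, seq, pos) {
  wb <- .seq_to_bits(as.character(word), "word")
  sb <- .seq_to_bits(seq)
  if (pos < 0 || pos + length(wb) > length(sb)) {
    stop(sprintf("match at 0-based position %d with word length %d exceeds sequence length %d",
                 pos, length(wb), length(sb)))
  }
  frag <- sb[(pos + 1L):(pos + length(wb))]
  all(bitwAnd(frag, bitwNot(wb)) == 0L)
}

#' A rigidly spaced composite sox--pax motif
#'
#' The unit of cryptic-site scanning: a sox half-site word, a fixed gap, and a
#' pax half-site word, in fixed order sox -> pax on the same strand. The pax
#' word may be used in `forward` orientation or `flipped` (reverse
#' complemented), modelling elements that encode the pax consensus on the
#' opposite strand.
#'
#' @param sox_word,pax_word IUPAC words (strings accepted).
#' @param gap Spacer length between the half-sites in bp (>= 0; overlapping
#'   half-sites are a construction-only concept and are never scanned).
#' @param pax_orientation `"forward"` or `"flipped"`.
#' @return An object of class `composite_motif`.
#' @examples
#' composite_motif("CATTGT", gap = 0, pax_word = "TGTTGC")
#' @export
composite_motif <- function(sox_word, gap = 0L, pax_word,
                            pax_orientation = c("forward", "flipped")) {
  pax_orientation <- match.arg(pax_orientation)
  if (!is.numeric(gap) || length(gap) != 1L || gap < 0 || gap != round(gap)) {
    stop("gap must be a single non-negative integer (overlapping half-sites are not scannable)")
  }
  structure(
    list(sox_word = iupac_word(as.character(sox_word)),
         pax_word = iupac_word(as.character(pax_word)),
         gap = as.integer(gap),
         pax_orientation = pax_orientation),
    class = "composite_motif"
  )
}

#' @export
print.composite_motif <- function(x, ...) {
  cat(sprintf("<composite_motif> %s -[%d bp]- %s (pax %s)\n",
              unclass(x$sox_word), x$gap, unclass(x$pax_word), x$pax_orientation))
  invisible(x)
}

#' Toggle the pax half-site orientation of a composite motif
#'
#' Returns the same motif with the pax word's orientation flipped, i.e. the
#' scanner will require the reverse complement of the pax word downstream of
#' the sox word. Applying the toggle twice restores the original motif.
#'
#' @param motif A [composite_motif()].
#' @return A [composite_motif()] with `pax_orientation` toggled.
#' @export
build_flipped_composite <- function(motif) {
  stopifnot(inherits(motif, "composite_motif"))
  motif$pax_orientation <- if (motif$pax_orientation == "forward") "flipped" else "forward"
  motif
}

#' Total span of a composite motif in bp
#' @param motif A [composite_motif()].
#' @return `len(sox) + gap + len(pax)`.
#' @export
motif_span <- function(motif) {
  nchar(motif$sox_word) + motif$gap + nchar(motif$pax_word)
}

# All 0-based offsets at which `word_bits` matches `seq_bits` (vectorised
# sliding subset test).
.word_offsets <- function(word_bits, seq_bits) {
  k <- length(word_bits); n <- length(seq_bits)
  if (n < k) return(integer(0))
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    ok <- ok & (bitwAnd(seq_bits[j:(n - k + j)], bitwNot(word_bits[j])) == 0L)
  }
  which(ok) - 1L
}

#' Scan a sequence for a composite motif
#'
#' Reports all and only the positions where the sox word matches and the pax
#' word (reverse-complemented first when `pax_orientation = "flipped"`)
#' matches at offset `len(sox) + gap` on the same strand. Minus-strand matches
#' of the whole composite are reported with `strand = "-"` and forward-strand
#' coordinates.
#'
#' @param motif A [composite_motif()].
#' @param seq Subject sequence (single string); lowercase (soft-masked) bases
#'   match unless `respect_mask = TRUE`.
#' @param seq_id Identifier recorded in the hits.
#' @param both_strands Scan the minus strand as well (default TRUE).
#' @param respect_mask If TRUE, soft-masked (lowercase) bases never match.
#' @return A data.frame of hits with columns `seq_id`, `offset` (0-based
#'   forward-strand coordinate of the sox word's first base as read on its
#'   strand), `strand`, `start`, `end` (0-based half-open matched span on the
#'   forward strand), sorted by `start` with `+` before `-` at ties.
#' @examples
#' m <- composite_motif("CATTGT", 0, "TGTTGC")
#' scan_composite(m, "TTCATTGTTGTTGCTCACCTACCATGGATCC")
#' @export
scan_composite <- function(motif, seq, seq_id = "seq", both_strands = TRUE,
                           respect_mask = FALSE) {
  stopifnot(inherits(motif, "composite_motif"))
  pax_eff <- if (motif$pax_orientation == "flipped") {
    reverse_complement(as.character(motif$pax_word))
  } else {
    as.character(motif$pax_word)
  }
  sox_bits <- .seq_to_bits(as.character(motif$sox_word), "word")
  pax_bits <- .seq_to_bits(pax_eff, "word")
  span <- length(sox_bits) + motif$gap + length(pax_bits)

  encode <- function(s) {
    b <- .seq_to_bits(s)
    if (respect_mask) {
      masked <- strsplit(s, "")[[1]] %in% letters  # lowercase = soft-masked
      b[masked] <- 16L  # fifth bit: not a subset of any word class, matches nothing
    }
    b
  }

  scan_strand <- function(bits) {
    n <- length(bits)
    if (n < span) return(integer(0))
    so <- .word_offsets(sox_bits, bits)
    shift <- length(sox_bits) + motif$gap
    po <- .word_offsets(pax_bits, bits)
    so[(so + shift) %in% po & (so + span) <= n]
  }

  n <- nchar(seq)
  plus <- scan_strand(encode(seq))
  hits <- data.frame(seq_id = character(0), offset = integer(0),
                     strand = character(0), start = integer(0), end = integer(0),
                     stringsAsFactors = FALSE)
  if (length(plus)) {
    hits <- data.frame(seq_id = seq_id, offset = plus, strand = "+",
                       start = plus, end = plus + span, stringsAsFactors = FALSE)
  }
  if (both_strands) {
    rc <- reverse_complement(seq)
    if (respect_mask) {
      # preserve the mask through the reverse complement
      mask <- rev(strsplit(seq, "")[[1]] %in% letters)
      rc_chars <- strsplit(rc, "")[[1]]
      rc_chars[mask] <- tolower(rc_chars[mask])
      rc <- paste(rc_chars, collapse = "")
    }
    minus <- scan_strand(encode(rc))
    if (length(minus)) {
      start <- n - (minus + span)  # forward-strand span start
      hits <- rbind(hits, data.frame(
        seq_id = seq_id,
        offset = start + motif$gap + length(pax_bits),  # sox-word start, fwd coords
        strand = "-", start = start, end = start + span,
        stringsAsFactors = FALSE))
    }
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a set of sequences for a composite motif
#'
#' @param motif A [composite_motif()].
#' @param seqs Named character vector of sequences (names become `seq_id`).
#' @param ... Passed to [scan_composite()].
#' @return Row-bound hit data.frame over all sequences.
#' @export
scan_composite_set <- function(motif, seqs, ...) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("seqs must be a named character vector")
  }
  out <- do.call(rbind, lapply(names(seqs), function(id) {
    scan_composite(motif, seqs[[id]], seq_id = id, ...)
  }))
  if (is.null(out)) {
    out <- data.frame(seq_id = character(0), offset = integer(0),
                      strand = character(0), start = integer(0), end = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Construct spacer variants of a composite element
#'
#' Builds the inter-half-site spacing series of a template element: for
#' positive deltas, bases are inserted at the junction between the sox
#' half-site and the spacer; for negative deltas, spacer bases adjacent to
#' that junction are deleted. Both half-site subsequences are preserved
#' verbatim in every variant; a deletion that would eat into a half-site is
#' refused. Inserted bases must be supplied explicitly.
#'
#' @param template The element sequence.
#' @param sox_span,pax_span 0-based half-open `c(start, end)` intervals of the
#'   half-sites within `template`; `sox_span[2] <= pax_span[1]`.
#' @param deltas Integer spacing changes (bp); 0 returns the template.
#' @param insert_bases String providing the bases inserted for positive
#'   deltas (first `delta` characters used); required if any delta > 0.
#' @return data.frame with columns `delta`, `label` (e.g. "+2"), `sequence`.
#' @export
enumerate_spacer_variants <- function(template, sox_span, pax_span, deltas,
                                      insert_bases = NULL) {
  n <- nchar(template)
  if (length(sox_span) != 2L || length(pax_span) != 2L ||
      sox_span[1] < 0 || sox_span[1] >= sox_span[2] ||
      pax_span[1] < sox_span[2] || pax_span[1] >= pax_span[2] || pax_span[2] > n) {
    stop("half-site spans must be valid 0-based half-open intervals with sox before pax")
  }
  gap_len <- pax_span[1] - sox_span[2]
  if (any(deltas != round(deltas))) stop("deltas must be integers")
  if (any(deltas > 0)) {
    if (is.null(insert_bases)) {
      stop("insert_bases must be supplied explicitly for positive deltas")
    }
    if (nchar(insert_bases) < max(deltas)) {
      stop("insert_bases shorter than the largest positive delta")
    }
    .seq_to_bits(insert_bases, "insert_bases")
  }
  junction <- sox_span[2]  # 0-based position right after the sox half-site
  pre <- substr(template, 1, junction)
  post <- substr(template, junction + 1, n)
  rows <- lapply(deltas, function(d) {
    if (d == 0) {
      s <- template
    } else if (d > 0) {
      s <- paste0(pre, substr(insert_bases, 1, d), post)
    } else {
      if (-d > gap_len) {
        stop(sprintf("delta %d would delete into a half-site (spacer is %d bp)",
                     d, gap_len))
      }
      s <- paste0(pre, substr(post, 1 - d, nchar(post)))
    }
    data.frame(delta = as.integer(d), label = sprintf("%+d", as.integer(d)),
               sequence = s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$label[out$delta == 0] <- "0"
  out
}

#' Enumerate nucleotide-switch mutants of a half-site
#'
#' Sequentially converts a degenerate (wild-type) half-site toward a consensus
#' half-site at a chosen set of switch positions, emitting every non-empty
#' position subset up to a maximum order. Variants are labelled in the
#' conventional style consensus-base + 1-based position (e.g. "G8C9" for the
#' double mutant at positions 8 and 9).
#'
#' @param wild_halfsite,consensus_halfsite Equal-length sequences.
#' @param positions 1-based switch positions within the half-site.
#' @param max_order Largest subset size to enumerate.
#' @return data.frame with columns `label`, `order`, `positions`
#'   (comma-separated), `sequence`.
#' @export
enumerate_switch_mutants <- function(wild_halfsite, consensus_halfsite,
                                     positions, max_order = length(positions)) {
  if (nchar(wild_halfsite) != nchar(consensus_halfsite)) {
    stop("wild and consensus half-sites must have equal length")
  }
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) == 0 || any(positions < 1) ||
      any(positions > nchar(wild_halfsite))) {
    stop("positions must be non-empty 1-based indices within the half-site")
  }
  w <- strsplit(toupper(wild_halfsite), "")[[1]]
  k <- strsplit(toupper(consensus_halfsite), "")[[1]]
  same <- positions[w[positions] == k[positions]]
  if (length(same)) {
    warning("wild and consensus agree at position(s) ",
            paste(same, collapse = ", "), "; subsets still emitted")
  }
  subsets <- unlist(lapply(seq_len(min(max_order, length(positions))), function(m) {
    utils::combn(positions, m, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(subsets, function(sub) {
    v <- w
    v[sub] <- k[sub]
    data.frame(
      label = paste0(k[sub], sub, collapse = ""),
      order = length(sub),
      positions = paste(sub, collapse = ","),
      sequence = paste(v, collapse = ""),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
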