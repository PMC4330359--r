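#' Parse a position frequency matrix in JASPAR text format
#'
#' Accepts the JASPAR PFM dialects: a `>` header line carrying the motif id,
#' followed by four rows labelled A, C, G, T with per-position counts,
#' optionally wrapped in square brackets:
#' \preformatted{>MA0069.1 Pax6
#' A [ 3  0 54 ... ]
#' C [ 1  2  0 ... ]
#' ...}
#'
#' @param text Character vector of lines, or a single string with embedded
#'   newlines.
#' @return An object of class `pfm`: list with `counts` (4 x L numeric matrix,
#'   rows A/C/G/T) and `motif_id`.
#' @export
parse_pfm <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  text <- trimws(text)
  text <- text[nzchar(text)]
  if (length(text) == 0) stop("empty PFM text")

  motif_id <- ""
  if (startsWith(text[1], ">")) {
    motif_id <- strsplit(sub("^>\\s*", "", text[1]), "\\s+")[[1]][1]
    text <- text[-1]
  }
  rows <- list()
  for (line in text) {
    m <- regmatches(line, regexec("^([ACGTacgt])\\s*\\[?\\s*([-0-9. \t]+?)\\s*\\]?\\s*$", line))[[1]]
    if (length(m) == 0) stop("unparseable PFM row: '", line, "'")
    base <- toupper(m[2])
    vals <- suppressWarnings(as.numeric(strsplit(m[3], "\\s+")[[1]]))
    if (anyNA(vals)) stop("non-numeric count in PFM row for base ", base)
    if (base %in% names(rows)) stop("duplicate PFM row for base ", base)
    rows[[base]] <- vals
  }
  missing <- setdiff(c("A", "C", "G", "T"), names(rows))
  if (length(missing)) stop("PFM missing row(s): ", paste(missing, collapse = ", "))
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) != 1L) stop("ragged PFM: rows have unequal lengths")
  counts <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
  if (any(counts < 0)) stop("negative counts in PFM")
  if (any(colSums(counts) <= 0)) stop("PFM column with zero total count")
  structure(list(counts = counts, motif_id = motif_id), class = "pfm")
}

#' Read a JASPAR PFM file
#' @param path Path to a JASPAR-format PFM text file.
#' @return A `pfm` object (see [parse_pfm()]).
#' @export
read_pfm <- function(path) parse_pfm(readLines(path, warn = FALSE))

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %s: %d positions\n",
              if (nzchar(x$motif_id)) x$motif_id else "(no id)", ncol(x$counts)))
  invisible(x)
}

#' Per-position information content of a PFM
#'
#' Shannon information content per position:
#' `IC = 2 + sum_b f_b log2 f_b` bits, where `f` is the pseudocount-smoothed
#' column frequency. At pseudocount 0 the values lie in `[0, 2]`; increasing
#' the pseudocount pulls every column toward the uniform value 0.
#'
#' @param pfm A `pfm` object.
#' @param pseudocount Added to every count (per base, per position) before
#'   normalisation; default 0.25, use 0 for exact small-matrix arithmetic.
#' @return Numeric vector of bits, one per position.
#' @export
information_content <- function(pfm, pseudocount = 0.25) {
  stopifnot(inherits(pfm, "pfm"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    stop("pseudocount must be a single non-negative number")
  }
  cts <- pfm$counts + pseudocount
  freq <- sweep(cts, 2, colSums(cts), "/")
  plogp <- ifelse(freq > 0, freq * log2(freq), 0)
  unname(2 + colSums(plogp))
}

#' Majority (consensus) base per PFM position
#' @param pfm A `pfm` object.
#' @return Character vector of bases; ties resolved in A,C,G,T order.
#' @export
pfm_consensus <- function(pfm) {
  stopifnot(inherits(pfm, "pfm"))
  rownames(pfm$counts)[apply(pfm$counts, 2, which.max)]
}

#' High-information positions where a half-site deviates from the PFM
#'
#' Identifies the candidate nucleotide-switch positions of a degenerate
#' half-site: positions whose PFM information content reaches `ic_threshold`
#' and whose half-site base is not a majority base of the PFM column. These
#' are the positions at which converting the degenerate site toward the
#' consensus is expected to change the binding mode.
#'
#' @param pfm A `pfm` object, same length as the half-site.
#' @param halfsite Half-site sequence (plain ACGT).
#' @param ic_threshold Information-content cutoff in bits.
#' @param pseudocount Passed to [information_content()]; default 0 so toy
#'   matrices give exact values.
#' @return Sorted integer vector of 1-based positions.
#' @export
high_ic_deviations <- function(pfm, halfsite, ic_threshold, pseudocount = 0) {
  stopifnot(inherits(pfm, "pfm"))
  if (nchar(halfsite) != ncol(pfm$counts)) {
    stop(sprintf("half-site length %d does not match PFM length %d",
                 nchar(halfsite), ncol(pfm$counts)))
  }
  bases <- strsplit(toupper(halfsite), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("half-site must be plain ACGT")
  }
  ic <- information_content(pfm, pseudocount = pseudocount)
  col_max <- apply(pfm$counts, 2, max)
  site_count <- pfm$counts[cbind(match(bases, rownames(pfm$counts)), seq_along(bases))]
  deviates <- site_count < col_max  # base is not (one of) the majority base(s)
  sort(which(ic >= ic_threshold & deviates))
}

#' Read a multi-record FASTA file
#' @param path FASTA file (wrapped or unwrapped).
#' @return Named character vector of uppercase-preserving sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs))) stop("seqs must be named")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}

#' Default degenerate composite-word configuration
#'
#' Loads the composite sox--pax word set shipped with the package for
#' DC5-like genome scanning. The shipped words are a reconstruction chosen to
#' match the canonical sox half-site and a degenerate pax half-site; they are
#' package defaults, not a published word list, and are marked as such in the
#' file itself.
#'
#' @param path Optional path to an alternative YAML config.
#' @return A [composite_motif()].
#' @export
dc5_like_motif <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dc5_like_words.yaml", package = "tfcoop")
  }
  cfg <- yaml::read_yaml(path)
  composite_motif(cfg$sox_word, gap = cfg$gap, pax_word = cfg$pax_word,
                  pax_orientation = cfg$pax_orientation)
}
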