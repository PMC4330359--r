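# Peak sets are held as GRanges (1-based closed internally, as GenomicRanges
# requires); the BED-facing interface is 0-based half-open.

#' Read a BED3+ file into a peak set
#'
#' Parses BED with 0-based half-open coordinates; `track` and `browser` lines
#' are tolerated and skipped. Malformed lines are reported with their line
#' number.
#'
#' @param path BED file path.
#' @param label Factor name attached to the peak set.
#' @return A `GRanges` with metadata column `name` (from BED column 4 when
#'   present) and attribute-free 1-based internal coordinates.
#' @export
read_bed <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$label <- label
    return(gr)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  parse_line <- function(f, ln) {
    if (length(f) < 3) stop(sprintf("BED line %d: fewer than 3 fields", ln))
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start != round(start) || end != round(end)) {
      stop(sprintf("BED line %d: non-integer coordinates '%s' '%s'", ln, f[2], f[3]))
    }
    if (start < 0) stop(sprintf("BED line %d: negative start", ln))
    if (start >= end) {
      stop(sprintf("BED line %d: start %d >= end %d", ln, as.integer(start), as.integer(end)))
    }
    c(f[1], start, end, if (length(f) >= 4) f[4] else NA_character_)
  }
  parsed <- mapply(parse_line, fields, idx, SIMPLIFY = FALSE)
  chrom <- vapply(parsed, `[`, character(1), 1)
  start0 <- as.numeric(vapply(parsed, `[`, character(1), 2))
  end0 <- as.numeric(vapply(parsed, `[`, character(1), 3))
  name <- vapply(parsed, `[`, character(1), 4)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    name = name
  )
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Write a peak set as BED
#'
#' @param peaks A `GRanges`.
#' @param path Output path.
#' @param names Optional names for BED column 4; defaults to the `name`
#'   metadata column when present (BED3 written otherwise).
#' @return Invisibly, `path`.
#' @export
write_bed <- function(peaks, path, names = NULL) {
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  start0 <- GenomicRanges::start(peaks) - 1L
  end0 <- GenomicRanges::end(peaks)
  if (is.null(names) && !is.null(peaks$name) && !all(is.na(peaks$name))) {
    names <- peaks$name
  }
  df <- if (is.null(names)) {
    data.frame(chrom, start0, end0)
  } else {
    data.frame(chrom, start0, end0, names)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a peak set from 0-based half-open coordinates
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end 0-based half-open coordinates (`start < end`).
#' @param name Optional region names.
#' @param label Factor name.
#' @return A `GRanges`.
#' @export
peak_set <- function(chrom, start, end, name = NA_character_, label = "") {
  if (any(start < 0) || any(start >= end)) {
    stop("intervals must satisfy 0 <= start < end")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end), name = name)
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Intersect two factors' peak sets into co-bound regions
#'
#' A co-bound region is the intersection span of every pair of peaks (one
#' from each factor) overlapping by at least `min_overlap` bp; spans that
#' themselves overlap are merged. The intersection-span convention is
#' conservative: every co-bound region is a subset of both factors' evidence.
#' Output is sorted and pairwise disjoint; the operation is symmetric in its
#' arguments.
#'
#' @param a,b `GRanges` peak sets.
#' @param min_overlap Minimum pairwise overlap in bp (default 1).
#' @param normalize_chr If TRUE, strip/ignore a `chr` prefix difference by
#'   normalising both sets to `chr`-prefixed names before matching; default
#'   FALSE (exact string equality).
#' @return A `GRanges` of co-bound regions.
#' @export
intersect_peaks <- function(a, b, min_overlap = 1L, normalize_chr = FALSE) {
  if (min_overlap < 1) stop("min_overlap must be >= 1 bp")
  norm <- function(g) {
    if (!normalize_chr) return(g)
    sn <- as.character(GenomicRanges::seqnames(g))
    sn <- ifelse(grepl("^chr", sn), sn, paste0("chr", sn))
    GenomicRanges::GRanges(sn, IRanges::ranges(g))
  }
  a <- norm(a); b <- norm(b)
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = as.integer(min_overlap))
  if (length(hits) == 0) return(GenomicRanges::GRanges())
  spans <- GenomicRanges::pintersect(a[S4Vectors::queryHits(hits)],
                                     b[S4Vectors::subjectHits(hits)])
  S4Vectors::mcols(spans) <- NULL
  GenomeInfoDb::seqlevels(spans) <- sort(GenomeInfoDb::seqlevels(spans))
  GenomicRanges::reduce(GenomicRanges::sort(spans))
}

#' Fraction of regions containing a motif
#'
#' Scans one sequence per region (both strands) for a composite motif or a
#' single degenerate word and reports how many regions carry at least one
#' hit.
#'
#' @param regions A `GRanges` of co-bound regions with non-NA `name`s, or a
#'   character vector of region ids.
#' @param sequences Named character vector, one sequence per region id.
#' @param motif A [composite_motif()] or an IUPAC word (string).
#' @return List with `n_regions`, `n_with_hit`, `fraction`, and `hits` (the
#'   per-region hit table).
#' @export
region_motif_fraction <- function(regions, sequences, motif) {
  ids <- if (methods::is(regions, "GRanges")) {
    if (is.null(regions$name) || anyNA(regions$name)) {
      stop("regions must carry names to match sequences")
    }
    regions$name
  } else {
    as.character(regions)
  }
  missing <- setdiff(ids, names(sequences))
  if (length(missing)) {
    stop("no sequence supplied for region(s): ", paste(missing, collapse = ", "))
  }
  if (!inherits(motif, "composite_motif")) {
    # single degenerate word: scan it as a composite with an empty pax part is
    # not possible, so scan the word directly on both strands
    word <- iupac_word(as.character(motif))
    hits <- do.call(rbind, lapply(ids, function(id) {
      seq <- sequences[[id]]
      wb <- .seq_to_bits(as.character(word), "word")
      plus <- .word_offsets(wb, .seq_to_bits(seq))
      minus <- .word_offsets(wb, .seq_to_bits(reverse_complement(seq)))
      n <- nchar(seq); k <- length(wb)
      rbind(
        if (length(plus)) data.frame(seq_id = id, offset = plus, strand = "+",
                                     start = plus, end = plus + k),
        if (length(minus)) data.frame(seq_id = id, offset = n - minus - k,
                                      strand = "-", start = n - minus - k,
                                      end = n - minus)
      )
    }))
    if (is.null(hits)) {
      hits <- data.frame(seq_id = character(0), offset = integer(0),
                         strand = character(0), start = integer(0), end = integer(0))
    }
  } else {
    hits <- scan_composite_set(motif, sequences[ids], both_strands = TRUE)
  }
  n_with <- length(unique(hits$seq_id))
  list(n_regions = length(ids), n_with_hit = n_with,
       fraction = n_with / length(ids), hits = hits)
}
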