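#' Normalize quantified gel-band intensities to microstate fractions
#'
#' Converts the four raw band intensities of one EMSA lane (free DNA,
#' Sox--DNA, Pax--DNA, ternary complex) into fractional occupancies by
#' dividing by the lane total. The result is exposure-invariant: scaling all
#' intensities by a common factor leaves the fractions unchanged.
#'
#' @param i_free,i_sox,i_pax,i_dimer Raw band intensities (arbitrary units,
#'   >= 0; at least one > 0).
#' @return A [microstate_fractions()] object.
#' @examples
#' normalize_lane(2, 4, 6, 8)
#' @export
normalize_lane <- function(i_free, i_sox, i_pax, i_dimer) {
  x <- c(i_free, i_sox, i_pax, i_dimer)
  if (length(x) != 4L || any(!is.finite(x)) || any(x < 0)) {
    stop("band intensities must be four finite non-negative numbers")
  }
  tot <- sum(x)
  if (tot <= 0) stop("all-zero lane: total intensity must be > 0")
  microstate_fractions(x[1] / tot, x[2] / tot, x[3] / tot, x[4] / tot)
}

#' Estimate the cooperativity factor omega from lane fractions
#'
#' The cooperativity factor is the ratio-of-ratios statistic
#' \deqn{\omega = \frac{f_{dimer} \, f_{free}}{f_{Sox} \, f_{Pax}}}
#' computed from the four microstate fractions of a single lane. An estimate
#' is flagged unreliable when any band it depends on falls below the
#' detectability threshold `epsilon`: a sub-threshold monomer band makes the
#' denominator untrustworthy, and a barely detectable ternary band (the
#' competitive-element situation) makes omega itself untrustworthy. A zero
#' denominator with `epsilon = 0` yields `Inf`, never an error.
#'
#' `log2_omega` is reported alongside: negative values (omega < 1) read as
#' competitive binding, zero as additive, positive as cooperative.
#'
#' @param fr A [microstate_fractions()] object (or a numeric vector with the
#'   four fractions in order free, sox, pax, dimer).
#' @param epsilon Detectability threshold in fraction units (default 0.01,
#'   i.e. 1% of the lane signal).
#' @return An object of class `coop_estimate`: list with `omega`,
#'   `log2_omega`, `reliable`, `unreliable_reason`.
#' @examples
#' estimate_omega(normalize_lane(0.05, 0.04, 0.01, 0.9), epsilon = 0)
#' @export
estimate_omega <- function(fr, epsilon = 0.01) {
  fr <- as.numeric(fr)
  if (length(fr) != 4L || any(!is.finite(fr)) || any(fr < 0)) {
    stop("fr must hold four finite non-negative fractions")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0) {
    stop("epsilon must be a single non-negative number")
  }
  f_free <- fr[1]; f_sox <- fr[2]; f_pax <- fr[3]; f_dimer <- fr[4]

  num <- f_dimer * f_free
  den <- f_sox * f_pax
  omega <- if (den > 0) num / den else if (num > 0) Inf else NaN

  reliable <- TRUE
  reason <- ""
  if (f_sox < epsilon || f_pax < epsilon) {
    reliable <- FALSE
    reason <- "monomer band below detectability"
  } else if (f_dimer < epsilon) {
    reliable <- FALSE
    reason <- "ternary band barely detectable"
  } else if (f_free < epsilon) {
    reliable <- FALSE
    reason <- "free-DNA band below detectability"
  }

  structure(
    list(omega = omega,
         log2_omega = if (is.finite(omega) && omega > 0) log2(omega)
                      else if (identical(omega, Inf)) Inf else NaN,
         reliable = reliable,
         unreliable_reason = reason),
    class = "coop_estimate"
  )
}

#' @export
print.coop_estimate <- function(x, ...) {
  cat(sprintf("<coop_estimate> omega = %.4g (log2 = %.3g)%s\n",
              x$omega, x$log2_omega,
              if (x$reliable) "" else paste0(" [unreliable: ", x$unreliable_reason, "]")))
  invisible(x)
}

#' Summarize replicate cooperativity estimates
#'
#' Aggregates per-lane omega estimates over replicates, using only reliable
#' estimates. The median and interquartile range are the primary summary (the
#' boxplot convention); mean and standard deviation are reported alongside
#' (the barplot-with-whiskers convention).
#'
#' @param estimates A list of `coop_estimate` objects (from
#'   [estimate_omega()]), or a numeric vector of omega values (all treated as
#'   reliable).
#' @return A one-row data.frame: `n` (reliable replicate count), `median`,
#'   `iqr_low`, `iqr_high` (25th/75th percentiles), `mean`, `sd`,
#'   `n_unreliable`.
#' @examples
#' summarize_replicates(c(10, 20, 30))
#' @export
summarize_replicates <- function(estimates) {
  if (is.numeric(estimates)) {
    if (length(estimates) == 0 || any(!is.finite(estimates)) || any(estimates < 0)) {
      stop("numeric omega values must be non-empty, finite and non-negative")
    }
    vals <- as.numeric(estimates)
    ok <- rep(TRUE, length(vals))
    reasons <- character(0)
  } else if (is.list(estimates) && length(estimates) > 0 &&
             all(vapply(estimates, inherits, logical(1), "coop_estimate"))) {
    ok <- vapply(estimates, function(e) isTRUE(e$reliable) && is.finite(e$omega),
                 logical(1))
    vals <- vapply(estimates[ok], function(e) e$omega, numeric(1))
    reasons <- vapply(estimates[!ok], function(e) e$unreliable_reason, character(1))
  } else {
    stop("estimates must be a non-empty list of coop_estimate objects or a numeric vector")
  }
  if (length(vals) == 0) {
    stop(paste0("no reliable estimates to summarize: ",
                paste(unique(reasons), collapse = "; ")))
  }
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(
    n = length(vals),
    median = q[2], iqr_low = q[1], iqr_high = q[3],
    mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else 0,
    n_unreliable = sum(!ok)
  )
}

#' Fit a dissociation constant to a titration curve
#'
#' Least-squares fit of the single-site isotherm
#' `bound = P / (P + Kd)` to (total protein, bound fraction) pairs, under the
#' trace-probe assumption (probe far below Kd, so total and free protein
#' coincide). Used to quantify reduced-affinity mutants from titration EMSAs.
#' The one-dimensional objective is minimised over log10(Kd) by bracketed
#' golden-section search, which cannot diverge.
#'
#' @param protein_total Numeric vector of total protein concentrations (nM),
#'   at least 3 distinct values.
#' @param bound_fraction Numeric vector of observed bound fractions, same
#'   length.
#' @param kd_range Search bracket for Kd (nM), default `c(1e-3, 1e9)`.
#' @return An object of class `kd_fit`: list with `kd_hat` (nM),
#'   `residual_norm` (L2 norm of residuals), `n_points`.
#' @examples
#' p <- c(25, 50, 100, 200, 400)
#' fit_kd(p, p / (p + 100))  # recovers Kd = 100
#' @export
fit_kd <- function(protein_total, bound_fraction, kd_range = c(1e-3, 1e9)) {
  p <- as.numeric(protein_total); b <- as.numeric(bound_fraction)
  if (length(p) != length(b)) stop("protein_total and bound_fraction lengths differ")
  if (length(unique(p)) < 3) stop("need at least 3 distinct protein concentrations")
  if (any(!is.finite(p)) || any(p < 0) || any(!is.finite(b))) {
    stop("titration points must be finite with non-negative concentrations")
  }
  if (all(b <= 0) || all(b >= 1)) {
    stop("degenerate titration: bound fractions all at 0 or all at saturation")
  }
  ssq <- function(log10_kd) {
    kd <- 10^log10_kd
    sum((b - p / (p + kd))^2)
  }
  opt <- stats::optimize(ssq, interval = log10(kd_range), tol = 1e-12)
  kd_hat <- 10^opt$minimum
  structure(
    list(kd_hat = kd_hat, residual_norm = sqrt(opt$objective), n_points = length(p)),
    class = "kd_fit"
  )
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit> Kd = %.4g nM (residual norm %.3g over %d points)\n",
              x$kd_hat, x$residual_norm, x$n_points))
  invisible(x)
}

#' Read a lane-quantification table
#'
#' Reads a TSV of quantified EMSA lanes with required header columns
#' `lane_id`, `element`, `replicate`, `i_free`, `i_sox`, `i_pax`, `i_dimer`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the seven columns, types checked.
#' @export
read_lanes_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("lane_id", "element", "replicate", "i_free", "i_sox", "i_pax", "i_dimer")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("lane table is missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("i_free", "i_sox", "i_pax", "i_dimer")) {
    if (!is.numeric(df[[col]])) stop("column ", col, " must be numeric")
    if (any(!is.finite(df[[col]])) || any(df[[col]] < 0)) {
      stop("column ", col, " must be finite and non-negative")
    }
  }
  df[need]
}

#' Per-element cooperativity estimates from a lane table
#'
#' Runs [normalize_lane()] + [estimate_omega()] on every lane of a lane table
#' and [summarize_replicates()] within each element.
#'
#' @param lanes A data.frame as returned by [read_lanes_tsv()].
#' @param epsilon Detectability threshold passed to [estimate_omega()].
#' @return A list with `per_lane` (data.frame: lane_id, element, replicate,
#'   omega, log2_omega, reliable, unreliable_reason) and `per_element`
#'   (data.frame of replicate summaries, one row per element; elements with no
#'   reliable lane get NA summaries and their reasons).
#' @export
estimate_omega_table <- function(lanes, epsilon = 0.01) {
  ests <- lapply(seq_len(nrow(lanes)), function(i) {
    estimate_omega(normalize_lane(lanes$i_free[i], lanes$i_sox[i],
                                  lanes$i_pax[i], lanes$i_dimer[i]),
                   epsilon = epsilon)
  })
  per_lane <- data.frame(
    lane_id = lanes$lane_id,
    element = lanes$element,
    replicate = lanes$replicate,
    omega = vapply(ests, function(e) e$omega, numeric(1)),
    log2_omega = vapply(ests, function(e) e$log2_omega, numeric(1)),
    reliable = vapply(ests, function(e) e$reliable, logical(1)),
    unreliable_reason = vapply(ests, function(e) e$unreliable_reason, character(1)),
    stringsAsFactors = FALSE
  )
  elements <- unique(per_lane$element)
  per_element <- do.call(rbind, lapply(elements, function(el) {
    sub <- ests[per_lane$element == el]
    summ <- tryCatch(summarize_replicates(sub), error = function(e) NULL)
    if (is.null(summ)) {
      data.frame(element = el, n = 0L, median = NA_real_, iqr_low = NA_real_,
                 iqr_high = NA_real_, mean = NA_real_, sd = NA_real_,
                 n_unreliable = length(sub),
                 note = paste(unique(vapply(sub, function(e) e$unreliable_reason,
                                            character(1))), collapse = "; "))
    } else {
      cbind(data.frame(element = el), summ, data.frame(note = ""))
    }
  }))
  list(per_lane = per_lane, per_element = per_element)
}
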