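#' Weighted amide chemical-shift perturbation
#'
#' Combines the amide proton and nitrogen shift changes between two states
#' into the standard weighted displacement
#' \deqn{\Delta\delta = \sqrt{(\Delta\delta_{HN})^2 + (0.1\,\Delta\delta_N)^2}}
#' in ppm. The nitrogen weight of 0.1 down-scales the wider 15N shift
#' dispersion; the result is sign-insensitive in both inputs.
#'
#' @param delta_h Amide 1H shift change (ppm); vectorised.
#' @param delta_n Amide 15N shift change (ppm); vectorised.
#' @param n_weight Nitrogen scaling factor (default 0.1).
#' @return Weighted CSP in ppm (>= 0).
#' @examples
#' weighted_csp(0.03, 0.4)  # 0.05
#' @export
weighted_csp <- function(delta_h, delta_n, n_weight = 0.1) {
  if (any(!is.finite(delta_h)) || any(!is.finite(delta_n))) {
    stop("shift changes must be finite")
  }
  sqrt(delta_h^2 + (n_weight * delta_n)^2)
}

#' Read a TSV peak list
#'
#' Plain-TSV peak-list dialect: header columns `residue_index`,
#' `residue_code`, `h_ppm`, `n_ppm`.
#'
#' @param path TSV path.
#' @return data.frame with the four columns.
#' @export
read_peaklist_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("residue_index", "residue_code", "h_ppm", "n_ppm")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("peak list missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$residue_index < 1) || any(df$residue_index != round(df$residue_index))) {
    stop("residue_index must be positive integers")
  }
  if (any(!is.finite(df$h_ppm)) || any(!is.finite(df$n_ppm))) {
    stop("shifts must be finite")
  }
  df[need]
}

#' Compare two titration states residue by residue
#'
#' Matches two peak lists (e.g. free protein vs protein--DNA complex) by
#' residue index and computes per-residue shift changes `state_b - state_a`
#' and the weighted CSP. Residues present in only one state are emitted with
#' a missing status and no weighted value. Swapping the states negates
#' `delta_h`/`delta_n` but leaves the weighted CSP unchanged.
#'
#' @param state_a,state_b data.frames as from [read_peaklist_tsv()]; residue
#'   indices must be unique within each state.
#' @param n_weight Passed to [weighted_csp()].
#' @return data.frame with columns `residue_index`, `residue_code`,
#'   `delta_h`, `delta_n`, `weighted`, `status`
#'   (`ok`/`missing_in_a`/`missing_in_b`), sorted by residue index.
#' @export
compare_states <- function(state_a, state_b, n_weight = 0.1) {
  for (nm in c("a", "b")) {
    st <- if (nm == "a") state_a else state_b
    if (anyDuplicated(st$residue_index)) {
      stop("duplicate residue_index in state_", nm, ": ",
           paste(unique(st$residue_index[duplicated(st$residue_index)]),
                 collapse = ", "))
    }
  }
  all_idx <- sort(union(state_a$residue_index, state_b$residue_index))
  ia <- match(all_idx, state_a$residue_index)
  ib <- match(all_idx, state_b$residue_index)
  status <- ifelse(is.na(ia), "missing_in_a",
                   ifelse(is.na(ib), "missing_in_b", "ok"))
  delta_h <- ifelse(status == "ok", state_b$h_ppm[ib] - state_a$h_ppm[ia], NA_real_)
  delta_n <- ifelse(status == "ok", state_b$n_ppm[ib] - state_a$n_ppm[ia], NA_real_)
  weighted <- ifelse(status == "ok", weighted_csp(
    ifelse(is.na(delta_h), 0, delta_h),
    ifelse(is.na(delta_n), 0, delta_n), n_weight = n_weight), NA_real_)
  code <- ifelse(!is.na(ia), state_a$residue_code[ia], state_b$residue_code[ib])
  data.frame(residue_index = all_idx, residue_code = code,
             delta_h = delta_h, delta_n = delta_n, weighted = weighted,
             status = status, stringsAsFactors = FALSE)
}

#' Classify significantly perturbed residues
#'
#' @param records data.frame from [compare_states()].
#' @param threshold Weighted-CSP cutoff in ppm (default 0.1, the conventional
#'   "large perturbation" line).
#' @return Sorted integer vector of residue indices with status `ok` and
#'   weighted CSP strictly above the threshold.
#' @export
classify_perturbed <- function(records, threshold = 0.1) {
  ok <- records$status == "ok" & !is.na(records$weighted)
  sort(records$residue_index[ok & records$weighted > threshold])
}
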