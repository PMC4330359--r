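#' Binding parameters for one composite DNA element
#'
#' Bundles the energetic description of a two-factor composite element: the
#' dissociation constant of the Sox factor for the element, the dissociation
#' constant of the Pax factor, and the cooperativity factor omega. Omega is the
#' ratio of the ternary-complex equilibrium constant to the product of the two
#' monomeric ones: omega > 1 means cooperative assembly, omega = 1 additive
#' (independent) binding, omega < 1 competitive binding.
#'
#' @param kd_sox Dissociation constant of Sox for the element (nM, > 0).
#' @param kd_pax Dissociation constant of Pax for the element (nM, > 0).
#' @param omega Cooperativity factor (dimensionless, > 0).
#' @param label Free-text element name (e.g. "DC5").
#' @return An object of class `binding_params`.
#' @examples
#' binding_params(kd_sox = 100, kd_pax = 1000, omega = 25, label = "DC5")
#' @export
binding_params <- function(kd_sox, kd_pax, omega, label = "") {
  for (v in list(kd_sox = kd_sox, kd_pax = kd_pax, omega = omega)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("kd_sox, kd_pax and omega must each be a single finite positive number")
    }
  }
  structure(
    list(kd_sox = as.numeric(kd_sox), kd_pax = as.numeric(kd_pax),
         omega = as.numeric(omega), label = as.character(label)),
    class = "binding_params"
  )
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("<binding_params> %s: Kd(Sox) = %g nM, Kd(Pax) = %g nM, omega = %g\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              x$kd_sox, x$kd_pax, x$omega))
  invisible(x)
}

#' Total species concentrations in a binding reaction
#'
#' @param dna_tot Total probe concentration (nM, >= 0).
#' @param sox_tot Total Sox concentration (nM, >= 0).
#' @param pax_tot Total Pax concentration (nM, >= 0).
#' @return An object of class `species_totals`.
#' @examples
#' species_totals(dna_tot = 300, sox_tot = 300, pax_tot = 300)
#' @export
species_totals <- function(dna_tot, sox_tot, pax_tot) {
  for (v in list(dna_tot = dna_tot, sox_tot = sox_tot, pax_tot = pax_tot)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("dna_tot, sox_tot and pax_tot must each be a single finite non-negative number")
    }
  }
  structure(
    list(dna_tot = as.numeric(dna_tot), sox_tot = as.numeric(sox_tot),
         pax_tot = as.numeric(pax_tot)),
    class = "species_totals"
  )
}

#' Microstate fractions of a DNA probe
#'
#' The probe in an EMSA lane partitions into four microstates that migrate as
#' distinct bands: free DNA, Sox-bound, Pax-bound and the ternary
#' Sox--Pax--DNA complex. Fractions must be in `[0, 1]` and sum to 1.
#'
#' @param f_free,f_sox,f_pax,f_dimer Fractional occupancies.
#' @param tol Tolerance on the unit-sum invariant.
#' @return An object of class `microstate_fractions` (a named numeric vector).
#' @export
microstate_fractions <- function(f_free, f_sox, f_pax, f_dimer, tol = 1e-9) {
  fr <- c(f_free = f_free, f_sox = f_sox, f_pax = f_pax, f_dimer = f_dimer)
  if (!all(is.finite(fr)) || any(fr < -tol) || any(fr > 1 + tol)) {
    stop("microstate fractions must be finite and in [0, 1]")
  }
  if (abs(sum(fr) - 1) > tol) {
    stop(sprintf("microstate fractions must sum to 1 (got %.12g)", sum(fr)))
  }
  structure(pmin(pmax(fr, 0), 1), class = "microstate_fractions")
}

#' @export
print.microstate_fractions <- function(x, ...) {
  cat(sprintf("<microstate_fractions> free %.4f | Sox %.4f | Pax %.4f | ternary %.4f\n",
              x[["f_free"]], x[["f_sox"]], x[["f_pax"]], x[["f_dimer"]]))
  invisible(x)
}

# Free DNA given free protein concentrations (closed form from DNA mass balance).
.free_dna <- function(dna_tot, s, p, ks, kp, w) {
  dna_tot / (1 + s / ks + p / kp + w * s * p / (ks * kp))
}

# Residual of the Pax mass balance at free concentrations (s, p); DNA eliminated.
.pax_residual <- function(p, s, params, totals) {
  d <- .free_dna(totals$dna_tot, s, p, params$kd_sox, params$kd_pax, params$omega)
  p * (1 + d / params$kd_pax + params$omega * s * d / (params$kd_sox * params$kd_pax)) -
    totals$pax_tot
}

# Residual of the Sox mass balance at free Sox s, with free Pax solved inwardly.
.sox_residual <- function(s, params, totals) {
  p <- .solve_free_pax(s, params, totals)
  d <- .free_dna(totals$dna_tot, s, p, params$kd_sox, params$kd_pax, params$omega)
  s * (1 + d / params$kd_sox + params$omega * p * d / (params$kd_sox * params$kd_pax)) -
    totals$sox_tot
}

.solve_free_pax <- function(s, params, totals) {
  if (totals$pax_tot == 0) return(0)
  # residual is < 0 at p = 0 and >= 0 at p = pax_tot: a physical root is bracketed
  stats::uniroot(.pax_residual, interval = c(0, totals$pax_tot),
                 s = s, params = params, totals = totals,
                 tol = max(1e-300, totals$pax_tot * 1e-14))$root
}

#' Solve the four-microstate equilibrium of two factors on one DNA probe
#'
#' Solves the coupled equilibria of Sox (S), Pax (P) and a DNA probe (D) under
#' full mass conservation, with complexes obeying
#' \deqn{[SD] = [S][D]/K_{d,Sox}, \quad [PD] = [P][D]/K_{d,Pax}, \quad
#'       [SPD] = \omega [S][P][D]/(K_{d,Sox} K_{d,Pax})}
#' at the free concentrations. No trace-probe approximation is made; the full
#' nonlinear system is solved by nested bounded root finding (each free
#' concentration bracketed in `[0, total]`, which always contains the physical
#' root), followed by validation of all three mass balances.
#'
#' An exact algebraic identity of this model is that the plug-in statistic
#' `(f_dimer * f_free) / (f_sox * f_pax)` of the returned fractions equals the
#' input omega.
#'
#' @param params A [binding_params()] object.
#' @param totals A [species_totals()] object; `dna_tot` must be > 0.
#' @param rel_tol Relative tolerance on each mass balance (default 1e-10).
#' @param max_iter Iteration cap for the polishing loop (default 10000).
#' @return A [microstate_fractions()] object with attribute `free`
#'   (named vector of free S, P, D in nM).
#' @examples
#' pr <- binding_params(100, 100, omega = 25)
#' fr <- solve_equilibrium(pr, species_totals(300, 300, 300))
#' (fr[["f_dimer"]] * fr[["f_free"]]) / (fr[["f_sox"]] * fr[["f_pax"]])  # = 25
#' @export
solve_equilibrium <- function(params, totals, rel_tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(params, "binding_params"), inherits(totals, "species_totals"))
  if (totals$dna_tot <= 0) stop("dna_tot must be > 0 to define probe fractions")

  s <- if (totals$sox_tot == 0) 0 else {
    stats::uniroot(.sox_residual, interval = c(0, totals$sox_tot),
                   params = params, totals = totals,
                   tol = max(1e-300, totals$sox_tot * 1e-14))$root
  }
  p <- .solve_free_pax(s, params, totals)
  d <- .free_dna(totals$dna_tot, s, p, params$kd_sox, params$kd_pax, params$omega)

  bal <- function(s, p, d) {
    ks <- params$kd_sox; kp <- params$kd_pax; w <- params$omega
    sd <- s * d / ks; pd <- p * d / kp; spd <- w * s * p * d / (ks * kp)
    c(dna = d + sd + pd + spd, sox = s + sd + spd, pax = p + pd + spd)
  }
  rel_err <- function(s, p, d) {
    got <- bal(s, p, d)
    want <- c(totals$dna_tot, totals$sox_tot, totals$pax_tot)
    max(abs(got - want) / pmax(want, .Machine$double.xmin))
  }

  # damped fixed-point polish; rarely needed after the nested root finding
  it <- 0L
  while (rel_err(s, p, d) > rel_tol && it < max_iter) {
    ks <- params$kd_sox; kp <- params$kd_pax; w <- params$omega
    s_new <- totals$sox_tot / (1 + d / ks + w * p * d / (ks * kp))
    p_new <- totals$pax_tot / (1 + d / kp + w * s * d / (ks * kp))
    s <- min(max(0.5 * (s + s_new), 0), totals$sox_tot)
    p <- min(max(0.5 * (p + p_new), 0), totals$pax_tot)
    d <- .free_dna(totals$dna_tot, s, p, ks, kp, w)
    it <- it + 1L
  }
  if (rel_err(s, p, d) > rel_tol) {
    stop(sprintf(
      "equilibrium solver did not converge (kd_sox=%g, kd_pax=%g, omega=%g, totals=%g/%g/%g)",
      params$kd_sox, params$kd_pax, params$omega,
      totals$dna_tot, totals$sox_tot, totals$pax_tot))
  }

  ks <- params$kd_sox; kp <- params$kd_pax; w <- params$omega
  fr <- microstate_fractions(
    f_free  = d / totals$dna_tot,
    f_sox   = s * d / ks / totals$dna_tot,
    f_pax   = p * d / kp / totals$dna_tot,
    f_dimer = w * s * p * d / (ks * kp) / totals$dna_tot
  )
  attr(fr, "free") <- c(sox = s, pax = p, dna = d)
  fr
}

#' Two differently labelled probes competing for shared protein pools
#'
#' Describes the dual-probe experiment in which two DNA elements with distinct
#' energetics (e.g. a cooperative low-affinity element and an additive
#' high-affinity element) are incubated simultaneously with shared Sox and Pax
#' pools, so the probes compete for the same free protein.
#'
#' @param probe_a,probe_b [binding_params()] for the two elements.
#' @param dna_tot_a,dna_tot_b Total concentration of each probe (nM, > 0).
#' @param sox_tot,pax_tot Shared protein pools (nM, >= 0).
#' @return An object of class `two_probe_system`.
#' @export
two_probe_system <- function(probe_a, probe_b, dna_tot_a, dna_tot_b,
                             sox_tot, pax_tot) {
  stopifnot(inherits(probe_a, "binding_params"), inherits(probe_b, "binding_params"))
  for (v in list(dna_tot_a = dna_tot_a, dna_tot_b = dna_tot_b)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("both probe totals must be single finite positive numbers")
    }
  }
  for (v in list(sox_tot = sox_tot, pax_tot = pax_tot)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("protein totals must be single finite non-negative numbers")
    }
  }
  structure(
    list(probe_a = probe_a, probe_b = probe_b,
         dna_tot_a = as.numeric(dna_tot_a), dna_tot_b = as.numeric(dna_tot_b),
         sox_tot = as.numeric(sox_tot), pax_tot = as.numeric(pax_tot)),
    class = "two_probe_system"
  )
}

#' Solve the coupled equilibrium of two competing probes
#'
#' As [solve_equilibrium()], but with two DNA probes drawing on the same free
#' Sox and Pax pools. Both probes see identical free protein concentrations;
#' the DNA mass balance holds per probe and the protein balances jointly.
#'
#' @param system A [two_probe_system()].
#' @param rel_tol Relative tolerance on every mass balance.
#' @param max_iter Iteration cap for the polishing loop.
#' @return A list with elements `a` and `b`, each a [microstate_fractions()],
#'   plus attribute `free` (shared free S, P).
#' @export
solve_two_probe <- function(system, rel_tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(system, "two_probe_system"))
  pa <- system$probe_a; pb <- system$probe_b

  free_d <- function(s, p) {
    c(a = .free_dna(system$dna_tot_a, s, p, pa$kd_sox, pa$kd_pax, pa$omega),
      b = .free_dna(system$dna_tot_b, s, p, pb$kd_sox, pb$kd_pax, pb$omega))
  }
  pax_res <- function(p, s) {
    d <- free_d(s, p)
    p * (1 +
           d[["a"]] / pa$kd_pax + pa$omega * s * d[["a"]] / (pa$kd_sox * pa$kd_pax) +
           d[["b"]] / pb$kd_pax + pb$omega * s * d[["b"]] / (pb$kd_sox * pb$kd_pax)) -
      system$pax_tot
  }
  solve_p <- function(s) {
    if (system$pax_tot == 0) return(0)
    stats::uniroot(pax_res, interval = c(0, system$pax_tot), s = s,
                   tol = max(1e-300, system$pax_tot * 1e-14))$root
  }
  sox_res <- function(s) {
    p <- solve_p(s)
    d <- free_d(s, p)
    s * (1 +
           d[["a"]] / pa$kd_sox + pa$omega * p * d[["a"]] / (pa$kd_sox * pa$kd_pax) +
           d[["b"]] / pb$kd_sox + pb$omega * p * d[["b"]] / (pb$kd_sox * pb$kd_pax)) -
      system$sox_tot
  }

  s <- if (system$sox_tot == 0) 0 else {
    stats::uniroot(sox_res, interval = c(0, system$sox_tot),
                   tol = max(1e-300, system$sox_tot * 1e-14))$root
  }
  p <- solve_p(s)
  d <- free_d(s, p)

  frac <- function(par, d_free, d_tot) {
    microstate_fractions(
      f_free  = d_free / d_tot,
      f_sox   = s * d_free / par$kd_sox / d_tot,
      f_pax   = p * d_free / par$kd_pax / d_tot,
      f_dimer = par$omega * s * p * d_free / (par$kd_sox * par$kd_pax) / d_tot
    )
  }
  out <- list(a = frac(pa, d[["a"]], system$dna_tot_a),
              b = frac(pb, d[["b"]], system$dna_tot_b))

  # joint validation of all four balances
  occ <- function(par, d_free) {
    sd <- s * d_free / par$kd_sox
    pd <- p * d_free / par$kd_pax
    spd <- par$omega * s * p * d_free / (par$kd_sox * par$kd_pax)
    c(dna = d_free + sd + pd + spd, sox = sd + spd, pax = pd + spd)
  }
  oa <- occ(pa, d[["a"]]); ob <- occ(pb, d[["b"]])
  got <- c(oa[["dna"]], ob[["dna"]],
           s + oa[["sox"]] + ob[["sox"]], p + oa[["pax"]] + ob[["pax"]])
  want <- c(system$dna_tot_a, system$dna_tot_b, system$sox_tot, system$pax_tot)
  if (max(abs(got - want) / pmax(want, .Machine$double.xmin)) > rel_tol) {
    stop(sprintf("two-probe solver did not reach rel_tol=%g for (%s | %s)",
                 rel_tol, pa$label, pb$label))
  }
  attr(out, "free") <- c(sox = s, pax = p)
  out
}

#' Titration series over one protein
#'
#' Solves the equilibrium along a grid of total concentrations of one protein,
#' keeping everything else fixed -- the in-silico analogue of a titration EMSA.
#'
#' @param params A [binding_params()].
#' @param base_totals A [species_totals()]; the varied species' entry is
#'   overwritten by the grid.
#' @param varying_species `"sox"` or `"pax"`.
#' @param grid Non-empty numeric vector of total concentrations (nM, >= 0).
#' @param rel_tol Passed to [solve_equilibrium()].
#' @return A data.frame with columns `conc`, `f_free`, `f_sox`, `f_pax`,
#'   `f_dimer`, one row per grid point in grid order.
#' @export
titration_series <- function(params, base_totals, varying_species = c("sox", "pax"),
                             grid, rel_tol = 1e-10) {
  varying_species <- match.arg(varying_species)
  if (length(grid) == 0 || any(!is.finite(grid)) || any(grid < 0)) {
    stop("grid must be a non-empty vector of finite non-negative concentrations")
  }
  rows <- lapply(seq_along(grid), function(i) {
    tot <- base_totals
    tot[[paste0(varying_species, "_tot")]] <- grid[i]
    fr <- tryCatch(solve_equilibrium(params, tot, rel_tol = rel_tol),
                   error = function(e) {
                     stop(sprintf("titration failed at grid point %d (%g nM): %s",
                                  i, grid[i], conditionMessage(e)))
                   })
    data.frame(conc = grid[i], f_free = fr[["f_free"]], f_sox = fr[["f_sox"]],
               f_pax = fr[["f_pax"]], f_dimer = fr[["f_dimer"]])
  })
  do.call(rbind, rows)
}

#' Read and write binding-parameter configurations
#'
#' Parameter sets are serialized as flat YAML key--value files with keys
#' `kd_sox`, `kd_pax`, `omega`, `label` (and optionally `dna_tot`,
#' `sox_tot`, `pax_tot` for totals).
#'
#' @param params A [binding_params()] object.
#' @param path File path.
#' @param totals Optional [species_totals()] written alongside.
#' @return `read_params_yaml()` returns a list with `params` and (if present
#'   in the file) `totals`; `write_params_yaml()` returns `path` invisibly.
#' @export
write_params_yaml <- function(params, path, totals = NULL) {
  stopifnot(inherits(params, "binding_params"))
  x <- list(kd_sox = params$kd_sox, kd_pax = params$kd_pax,
            omega = params$omega, label = params$label)
  if (!is.null(totals)) {
    stopifnot(inherits(totals, "species_totals"))
    x <- c(x, list(dna_tot = totals$dna_tot, sox_tot = totals$sox_tot,
                   pax_tot = totals$pax_tot))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  out <- list(params = binding_params(x$kd_sox, x$kd_pax, x$omega,
                                      label = if (is.null(x$label)) "" else x$label))
  if (!is.null(x$dna_tot)) {
    out$totals <- species_totals(x$dna_tot, x$sox_tot, x$pax_tot)
  }
  out
}

#' Closed-form single-site bound fraction
#'
#' Langmuir isotherm `P / (P + Kd)` for one protein binding one site at free
#' protein concentration `P`; the exact single-protein, trace-probe limit of
#' the full equilibrium solver.
#'
#' @param kd Dissociation constant (nM, > 0).
#' @param protein_free Free protein concentration (nM, >= 0); vectorised.
#' @return Bound fraction(s) in `[0, 1]`.
#' @examples
#' fraction_bound_single(100, 100)  # 0.5
#' @export
fraction_bound_single <- function(kd, protein_free) {
  if (!is.numeric(kd) || length(kd) != 1L || !is.finite(kd) || kd <= 0) {
    stop("kd must be a single finite positive number")
  }
  if (any(!is.finite(protein_free)) || any(protein_free < 0)) {
    stop("protein_free must be finite and non-negative")
  }
  protein_free / (protein_free + kd)
}
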