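test_that("limit cases: no protein and vanishing affinity leave the probe free", {
  pr <- binding_params(100, 100, 25)
  fr0 <- solve_equilibrium(pr, species_totals(300, 0, 0))
  expect_equal(as.numeric(fr0), c(1, 0, 0, 0))

  weak <- binding_params(1e12, 1e12, 1)
  fr <- solve_equilibrium(weak, species_totals(300, 300, 300))
  expect_lt(abs(fr[["f_free"]] - 1), 1e-6)
})

test_that("input validation rejects unphysical parameters and totals", {
  expect_error(binding_params(-1, 100, 25), "positive")
  expect_error(binding_params(100, 100, 0), "positive")
  expect_error(species_totals(-1, 0, 0), "non-negative")
  expect_error(solve_equilibrium(binding_params(100, 100, 1),
                                 species_totals(0, 10, 10)),
               "dna_tot")
})

test_that("mass balances hold at the returned free concentrations", {
  set.seed(101)
  for (i in 1:25) {
    pr <- binding_params(runif(1, 10, 1e4), runif(1, 10, 1e4),
                         exp(runif(1, log(0.1), log(100))))
    tot <- species_totals(runif(1, 10, 1000), runif(1, 10, 1000),
                          runif(1, 10, 1000))
    fr <- solve_equilibrium(pr, tot, rel_tol = 1e-10)
    free <- attr(fr, "free")
    s <- free[["sox"]]; p <- free[["pax"]]; d <- free[["dna"]]
    sd <- s * d / pr$kd_sox
    pd <- p * d / pr$kd_pax
    spd <- pr$omega * s * p * d / (pr$kd_sox * pr$kd_pax)
    expect_lt(abs(d + sd + pd + spd - tot$dna_tot) / tot$dna_tot, 1e-10)
    expect_lt(abs(s + sd + spd - tot$sox_tot) / tot$sox_tot, 1e-10)
    expect_lt(abs(p + pd + spd - tot$pax_tot) / tot$pax_tot, 1e-10)
    expect_equal(sum(as.numeric(fr)), 1, tolerance = 1e-9)
  }
})

test_that("plug-in omega of solver output equals the input omega (round trip)", {
  set.seed(7)
  for (i in 1:50) {
    w <- exp(runif(1, log(0.1), log(100)))
    pr <- binding_params(runif(1, 10, 1e4), runif(1, 10, 1e4), w)
    tot <- species_totals(runif(1, 10, 1000), runif(1, 10, 1000),
                          runif(1, 10, 1000))
    fr <- solve_equilibrium(pr, tot)
    w_hat <- (fr[["f_dimer"]] * fr[["f_free"]]) / (fr[["f_sox"]] * fr[["f_pax"]])
    expect_lt(abs(w_hat - w) / w, 1e-6)
  }
})

test_that("omega = 1 factorizes the microstate fractions", {
  fr <- solve_equilibrium(binding_params(200, 400, 1),
                          species_totals(300, 250, 500))
  expect_equal(fr[["f_dimer"]] * fr[["f_free"]], fr[["f_sox"]] * fr[["f_pax"]],
               tolerance = 1e-9)
})

test_that("solver agrees with the independent Newton oracle on random instances", {
  set.seed(42)
  for (i in 1:100) {
    pr <- binding_params(runif(1, 10, 1e4), runif(1, 10, 1e4),
                         exp(runif(1, log(0.1), log(100))))
    tot <- species_totals(runif(1, 10, 1000), runif(1, 10, 1000),
                          runif(1, 10, 1000))
    got <- as.numeric(solve_equilibrium(pr, tot))
    want <- as.numeric(oracle_equilibrium(pr, tot))
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("two-probe solve is symmetric and reduces to single-probe limits", {
  pr <- binding_params(100, 100, 25, "x")
  sys <- two_probe_system(pr, pr, 300, 300, 300, 300)
  tp <- solve_two_probe(sys)
  expect_equal(as.numeric(tp$a), as.numeric(tp$b), tolerance = 1e-9)

  # vanishing competitor: probe_a behaves as in a single-probe solve
  sys2 <- two_probe_system(pr, binding_params(50, 50, 2), 300, 1e-9, 300, 300)
  tp2 <- solve_two_probe(sys2)
  single <- solve_equilibrium(pr, species_totals(300, 300, 300))
  expect_lt(max(abs(as.numeric(tp2$a) - as.numeric(single))), 1e-6)
})

test_that("cooperative and additive probes partition shared pools as expected", {
  # low Sox: the additive high-affinity probe accumulates the Pax monomer band,
  # the cooperative probe accumulates the ternary band
  sys <- two_probe_system(binding_params(100, 1000, 25, "DC5-like"),
                          binding_params(100, 100, 1, "DC5con-like"),
                          300, 300, sox_tot = 100, pax_tot = 300)
  tp <- solve_two_probe(sys)
  expect_gt(tp$a[["f_dimer"]], tp$a[["f_pax"]])
  expect_gt(tp$b[["f_pax"]], tp$b[["f_dimer"]])
})

test_that("titration series is grid-ordered with monotone bound fraction", {
  pr <- binding_params(100, 100, 25)
  base <- species_totals(300, 0, 200)
  one <- titration_series(pr, base, "sox", grid = 0)
  expect_equal(nrow(one), 1L)
  expect_equal(as.numeric(one[1, -1]),
               as.numeric(solve_equilibrium(pr, species_totals(300, 0, 200))))

  grid <- c(0, 25, 50, 100, 200, 400, 600)
  ts <- titration_series(pr, base, "sox", grid = grid)
  expect_equal(ts$conc, grid)
  bound <- 1 - ts$f_free
  expect_true(all(diff(bound) >= -1e-12))
})

test_that("parameter sets round-trip through YAML config", {
  pr <- binding_params(100, 1000, 25, "DC5")
  tot <- species_totals(300, 300, 300)
  f <- tempfile(fileext = ".yaml")
  write_params_yaml(pr, f, totals = tot)
  back <- read_params_yaml(f)
  expect_equal(back$params, pr)
  expect_equal(back$totals, tot)
})

test_that("trace-probe titration reproduces the closed-form isotherm", {
  pr <- binding_params(100, 100, 25)
  ts <- titration_series(pr, species_totals(1e-6, 0, 0), "sox", grid = 100)
  expect_equal(ts$f_sox, 0.5, tolerance = 1e-6)

  expect_equal(fraction_bound_single(100, 100), 0.5)
  expect_equal(fraction_bound_single(100, 0), 0)
  expect_equal(fraction_bound_single(50, 150), 0.75)
  expect_error(fraction_bound_single(100, -1), "non-negative")
})
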