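test_that("lane normalization divides by the lane total", {
  expect_equal(as.numeric(normalize_lane(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(as.numeric(normalize_lane(9, 0, 0, 1)), c(0.9, 0, 0, 0.1))
  expect_equal(as.numeric(normalize_lane(2, 4, 6, 8)), c(0.1, 0.2, 0.3, 0.4))
  expect_error(normalize_lane(0, 0, 0, 0), "all-zero")
})

test_that("omega is invariant to lane exposure (scale invariance)", {
  set.seed(5)
  for (i in 1:20) {
    x <- runif(4, 0.01, 10)
    c_scale <- runif(1, 1e-3, 1e3)
    e1 <- estimate_omega(normalize_lane(x[1], x[2], x[3], x[4]), epsilon = 0)
    e2 <- estimate_omega(normalize_lane(c_scale * x[1], c_scale * x[2],
                                        c_scale * x[3], c_scale * x[4]),
                         epsilon = 0)
    expect_equal(e1$omega, e2$omega, tolerance = 1e-12)
  }
})

test_that("omega statistic matches hand-computed and model-derived values", {
  e <- estimate_omega(microstate_fractions(0.25, 0.25, 0.25, 0.25))
  expect_equal(e$omega, 1)
  expect_equal(e$log2_omega, 0)
  expect_true(e$reliable)

  e2 <- estimate_omega(microstate_fractions(0.05, 0.04, 0.01, 0.9), epsilon = 0)
  expect_equal(e2$omega, 112.5)

  fr <- solve_equilibrium(binding_params(150, 700, 25),
                          species_totals(300, 250, 400))
  expect_equal(estimate_omega(fr)$omega, 25, tolerance = 1e-6)
})

test_that("sub-threshold bands flag the estimate instead of erroring", {
  # zero denominator with epsilon = 0: flagged infinite, no exception
  e <- estimate_omega(c(0.5, 0, 0.2, 0.3), epsilon = 0)
  expect_identical(e$omega, Inf)

  # a competitive element with a barely detectable ternary band (LE9-like)
  le9 <- get_preset("LE9")
  fr <- solve_equilibrium(le9$params, species_totals(300, 300, 300))
  expect_lt(fr[["f_dimer"]], 0.01)
  e2 <- estimate_omega(fr, epsilon = 0.01)
  expect_false(e2$reliable)
  expect_match(e2$unreliable_reason, "ternary band")

  # a sub-threshold monomer band
  e3 <- estimate_omega(c(0.1, 0.005, 0.2, 0.695), epsilon = 0.01)
  expect_false(e3$reliable)
  expect_match(e3$unreliable_reason, "monomer band")
})

test_that("replicate summaries use reliable estimates and are permutation-invariant", {
  expect_equal(summarize_replicates(c(1, 1, 1))$median, 1)
  expect_equal(summarize_replicates(c(1, 1, 1))$iqr_high -
                 summarize_replicates(c(1, 1, 1))$iqr_low, 0)
  expect_equal(summarize_replicates(c(10, 20, 30))$median, 20)

  set.seed(9)
  vals <- runif(11, 1, 50)
  s1 <- summarize_replicates(vals)
  s2 <- summarize_replicates(sample(vals))
  expect_equal(s1, s2)

  bad <- lapply(1:3, function(i) estimate_omega(c(0.6, 0.001, 0.3, 0.099),
                                                epsilon = 0.01))
  expect_error(summarize_replicates(bad), "monomer band")
})

test_that("median omega over 10 noisy replicates recovers the cooperative regime", {
  # bounds calibrated by 10,000-draw simulation of the median under the
  # lognormal band-noise model (CV 0.1, n = 10, omega_true = 25)
  dc5 <- get_preset("DC5")
  lanes <- simulate_gel_replicates(dc5$params, species_totals(300, 300, 300),
                                   n_replicates = 10, noise_cv = 0.1, seed = 42)
  summ <- summarize_replicates(omega_from_lanes(lanes))
  expect_gte(summ$median, 20)
  expect_lte(summ$median, 31)
  expect_equal(summ$n, 10L)
})

test_that("omega estimator is median-unbiased under the band-noise model", {
  tot <- species_totals(300, 300, 300)
  for (w in c(1, 25, 50)) {
    pr <- binding_params(100, 300, w)
    lanes <- simulate_gel_replicates(pr, tot, n_replicates = 200,
                                     noise_cv = 0.1, seed = 2024)
    med <- summarize_replicates(omega_from_lanes(lanes, epsilon = 0))$median
    expect_lt(abs(med - w) / w, 0.10)
  }
})

test_that("Kd fitting recovers exact and noisy titrations", {
  p <- c(25, 100, 400)
  fit <- fit_kd(p, p / (p + 100))
  expect_equal(fit$kd_hat, 100, tolerance = 1e-6)
  expect_equal(fit$n_points, 3L)

  expect_error(fit_kd(100, 0.5), "at least 3")
  expect_error(fit_kd(c(25, 100, 400), c(0, 0, 0)), "degenerate")

  # 8-point titration, Kd 250, multiplicative noise CV 0.05, seed 7;
  # 10% tolerance calibrated by repeated simulation
  set.seed(7)
  pt <- c(25, 50, 100, 200, 400, 800, 1600, 3200)
  b <- pt / (pt + 250) * exp(rnorm(8, 0, sqrt(log(1 + 0.05^2))))
  fit2 <- fit_kd(pt, pmin(b, 1))
  expect_lt(abs(fit2$kd_hat - 250) / 250, 0.10)
})

test_that("lane tables round-trip through TSV and group by element", {
  lanes <- rbind(
    simulate_gel_replicates(get_preset("DC5")$params,
                            species_totals(300, 300, 300),
                            n_replicates = 3, noise_cv = 0.05, seed = 3),
    simulate_gel_replicates(get_preset("DC5con")$params,
                            species_totals(300, 300, 300),
                            n_replicates = 3, noise_cv = 0.05, seed = 4)
  )
  tsv <- tempfile(fileext = ".tsv")
  write.table(lanes, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_lanes_tsv(tsv)
  expect_equal(nrow(back), 6L)

  res <- estimate_omega_table(back, epsilon = 0.01)
  expect_equal(nrow(res$per_lane), 6L)
  expect_setequal(res$per_element$element, c("DC5", "DC5con"))
  med_dc5 <- res$per_element$median[res$per_element$element == "DC5"]
  med_con <- res$per_element$median[res$per_element$element == "DC5con"]
  expect_gt(med_dc5, med_con)

  expect_error(read_lanes_tsv({
    f <- tempfile(); writeLines("lane_id\ti_free", f); f
  }), "missing required column")
})
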