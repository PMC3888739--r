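test_that("fit_rle recovers an exactly linear series and flags screening cases", {
  s <- make_rle_series(a = -100, b = 300, times = c(1, 2, 4))
  f <- fit_rle(s)
  expect_equal(f$fit$slope_a, -100)
  expect_equal(f$fit$intercept_b, 300)
  expect_equal(f$fit$r_squared, 1)
  expect_length(f$screen_flags, 0L)

  const <- toxicity_series("sp", "tox", c(1, 2, 4), c(50, 50, 50))
  fc <- fit_rle(const)
  expect_true("constant_lc50" %in% fc$screen_flags)

  rising <- toxicity_series("sp", "tox", c(1, 2, 4), c(10, 20, 40))
  expect_true("nonneg_slope" %in% fit_rle(rising)$screen_flags)

  set.seed(5)
  noisy <- toxicity_series("sp", "tox", c(1, 2, 4), abs(rnorm(3, 50, 40)))
  # low_r2 flag tracks the configurable threshold
  f_lo <- fit_rle(noisy, r2_threshold = 0.999)
  expect_true("low_r2" %in% f_lo$screen_flags ||
                f_lo$fit$r_squared >= 0.999)
})

test_that("fit_rle on noisy synthetic data equals OLS of the identical points", {
  gs <- generate_series(synthetic_config(n_series = 1, seed = 1, noise_sd = 5))
  f <- fit_rle(gs[[1]])
  o <- ols_oracle(log(gs[[1]]$records$time_days), gs[[1]]$records$lc50_ugL)
  expect_equal(f$fit$slope_a, o$slope, tolerance = 1e-12)
  expect_equal(f$fit$intercept_b, o$intercept, tolerance = 1e-12)
})

test_that("ln NLT is -b/a, with precondition errors for flat or inverted fits", {
  est <- ln_nlt_from_fit(rle_fit_from_coeffs(-9400, 100000))
  expect_equal(est$ln_nlt, 100000 / 9400)   # 10.638...
  expect_equal(est$nlt_days, exp(est$ln_nlt))
  expect_equal(est$method, "coefficients")

  unit <- ln_nlt_from_fit(rle_fit_from_coeffs(-1, 1))
  expect_equal(unit$ln_nlt, 1)
  expect_equal(unit$nlt_days, exp(1))

  expect_error(ln_nlt_from_fit(rle_fit_from_coeffs(-1, 0)),
               class = "rletox_negative_extrapolation")
  expect_error(ln_nlt_from_fit(rle_fit_from_coeffs(0.5, 10)),
               class = "rletox_no_toxicity_trend")
})

test_that("ln NLT is invariant under rescaling of the concentration axis", {
  for (c_scale in c(0.001, 0.5, 1000)) {
    f1 <- rle_fit_from_coeffs(-130, 580)
    f2 <- rle_fit_from_coeffs(-130 * c_scale, 580 * c_scale)
    expect_equal(ln_nlt_from_fit(f2)$ln_nlt, ln_nlt_from_fit(f1)$ln_nlt)
    # d scales inversely with concentration
    expect_equal(toxicity_constant(f2)$d_value,
                 toxicity_constant(f1)$d_value / c_scale)
  }
})

test_that("the toxicity constant is -1/a", {
  expect_equal(toxicity_constant(rle_fit_from_coeffs(-0.5, 1))$d_value, 2)
  expect_equal(toxicity_constant(rle_fit_from_coeffs(-9400, 1))$d_value,
               1 / 9400)
  expect_error(toxicity_constant(rle_fit_from_coeffs(0, 1)),
               class = "rletox_no_toxicity_trend")
})

test_that("predict_lc50 evaluates the line, is b at 1 day, 0 at the NLT, floored beyond", {
  f <- rle_fit_from_coeffs(-5800, 36000)
  expect_equal(as.numeric(predict_lc50(f, 1)), 36000)
  expect_equal(as.numeric(predict_lc50(f, 4)), 36000 - 5800 * log(4))
  nlt <- exp(36000 / 5800)
  expect_equal(as.numeric(predict_lc50(f, nlt)), 0)
  p <- predict_lc50(f, nlt * 2)
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "beyond_nlt"))
  expect_error(predict_lc50(f, 0), class = "rletox_bad_input")
})

test_that("predict_lt50 returns the NLT at zero concentration and 1 day at c = b", {
  f <- rle_fit_from_coeffs(-5800, 36000)
  p0 <- predict_lt50(f, 0)
  expect_equal(p0$lt50_days, exp(36000 / 5800))
  expect_equal(p0$fraction_of_nlt, 1)
  expect_equal(predict_lt50(f, 36000)$lt50_days, 1)
  expect_error(predict_lt50(rle_fit_from_coeffs(2, 10), 5),
               class = "rletox_no_toxicity_trend")
})

test_that("predict_lc50 and predict_lt50 are mutually inverse on (0, b)", {
  f <- rle_fit_from_coeffs(-5800, 36000)
  cs <- seq(1, 35999, length.out = 50)
  back <- as.numeric(predict_lc50(f, predict_lt50(f, cs)$lt50_days))
  expect_lt(max(abs(back - cs) / cs), 1e-9)
})

test_that("predictions are strictly monotone in their arguments", {
  f <- rle_fit_from_coeffs(-100, 300)
  nlt <- exp(3)
  t_grid <- seq(0.01, nlt * 0.999, length.out = 200)
  expect_true(all(diff(as.numeric(predict_lc50(f, t_grid))) < 0))
  c_grid <- seq(0, 299, length.out = 200)
  expect_true(all(diff(predict_lt50(f, c_grid)$lt50_days) < 0))
})

test_that("two-point fits interpolate both anchors and invert the worked prediction", {
  # round numbers: ln NLT - ln t = 2
  f <- two_point_fit(100, 4, 4 * exp(2))
  expect_equal(f$fit$slope_a, -50)
  expect_equal(f$fit$intercept_b, 50 * (log(4) + 2))
  expect_equal(as.numeric(predict_lc50(f, 4)), 100)
  expect_equal(as.numeric(predict_lc50(f, 4 * exp(2))), 0)
  expect_equal(f$method, "two_point")

  # inverse of the evaluated prediction recovers its coefficients
  lc96 <- 36000 - 5800 * log(4)
  f2 <- two_point_fit(lc96, 4, exp(36000 / 5800))
  expect_equal(f2$fit$slope_a, -5800)
  expect_equal(f2$fit$intercept_b, 36000)

  expect_error(two_point_fit(100, 10, 5), class = "rletox_inconsistent_inputs")
  expect_error(two_point_fit(0, 1, 10), class = "rletox_bad_input")
})

test_that("unit invariance holds across a whole fitted series", {
  s <- make_rle_series(a = -40, b = 450, times = c(1, 2, 3, 4))
  s_mg <- toxicity_series(s$species, s$toxicant, s$records$time_days,
                          s$records$lc50_ugL / 1000)
  f <- fit_rle(s); f_mg <- fit_rle(s_mg)
  expect_equal(f_mg$fit$slope_a, f$fit$slope_a / 1000)
  expect_equal(ln_nlt_from_fit(f_mg)$ln_nlt, ln_nlt_from_fit(f)$ln_nlt)
  expect_equal(predict_lt50(f_mg, 0.123)$lt50_days,
               predict_lt50(f, 123)$lt50_days)
  expect_equal(predict_lt50(f_mg, 0.123)$fraction_of_nlt,
               predict_lt50(f, 123)$fraction_of_nlt)
})

test_that("species averaging is an ln-scale mean with a dataset minimum", {
  f <- rle_fit_from_coeffs(-2, 6, species = "sp")   # ln NLT = 3
  est <- species_calculated_nlt(list(f, f, f, f))
  expect_equal(est$ln_nlt, 3)
  expect_equal(est$nlt_days, exp(3))
  expect_equal(est$n_datasets, 4L)
  expect_equal(est$method, "species_average")

  expect_error(species_calculated_nlt(list(f, f, f)),
               class = "rletox_insufficient_datasets")
  expect_equal(species_calculated_nlt(list(f, f, f), min_datasets = 2)$n_datasets, 3L)
  g <- rle_fit_from_coeffs(-2, 6, species = "other")
  expect_error(species_calculated_nlt(list(f, f, f, g)),
               class = "rletox_bad_input")
  # flagged no-trend fits are not usable datasets
  h <- rle_fit_from_coeffs(2, 6, species = "sp")
  expect_error(species_calculated_nlt(list(f, f, f, h)),
               class = "rletox_insufficient_datasets")
})

test_that("the r2_min filter drops weak datasets before averaging", {
  mk <- function(lnn, r2) rle_fit_from_coeffs(-1, lnn, species = "sp",
                                              r_squared = r2)
  fits <- list(mk(2, 0.95), mk(4, 0.95), mk(6, 0.95), mk(8, 0.95), mk(100, 0.5))
  expect_equal(species_calculated_nlt(fits)$ln_nlt, 24)  # all five included
  expect_equal(species_calculated_nlt(fits, r2_min = 0.8)$ln_nlt, 5)
})

test_that("internal concentrations scale by the bioconcentration factor without moving ln NLT", {
  expect_equal(internal_from_ambient(100, 10), 1000)
  expect_equal(internal_from_ambient(0, 5), 0)
  expect_error(internal_from_ambient(10, 0), class = "rletox_bad_input")
  expect_error(internal_from_ambient(-1, 2), class = "rletox_bad_input")
  # refitting on the internal scale leaves the extrapolated NLT unchanged
  s <- make_rle_series(a = -100, b = 300, times = c(1, 2, 3, 4))
  s_int <- toxicity_series(s$species, s$toxicant, s$records$time_days,
                           internal_from_ambient(s$records$lc50_ugL, k_b = 37))
  expect_equal(ln_nlt_from_fit(fit_rle(s_int))$ln_nlt,
               ln_nlt_from_fit(fit_rle(s))$ln_nlt)
})

test_that("reported-vs-calculated comparison is a through-origin fit on both scales", {
  out <- compare_reported_vs_calculated(c(100, 200, 300), c(100, 200, 300))
  expect_equal(out$day$slope, 1)
  expect_equal(out$day$r_squared, 1)
  expect_equal(out$ln$slope, 1)

  out2 <- compare_reported_vs_calculated(c(1, 2), c(2, 3))
  expect_equal(out2$day$slope, 8 / 5)
  expect_error(compare_reported_vs_calculated(1, 2),
               class = "rletox_insufficient_data")
})

test_that("fixture species pairs give a ln-scale slope near 1, matching a direct oracle", {
  tab <- load_table1_fixture()
  nlt_tab <- species_nlt_table(fixture_fits(tab))
  ok <- nlt_tab[nlt_tab$status == "ok", ]
  reported <- vapply(ok$species, function(s)
    tab$reported_nlt_days[tab$species == s][1], numeric(1))
  out <- compare_reported_vs_calculated(ok$nlt_days, reported)
  expect_equal(out$ln$slope,
               origin_oracle(log(ok$nlt_days), log(reported)))
  expect_gt(out$ln$slope, 0.9)
  expect_lt(out$ln$slope, 1.1)
})
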