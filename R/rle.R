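# The reduced life expectancy (RLE) model.
#
# LC50 = a ln(LT50) + b with a < 0; the x-intercept exp(-b/a) is the species'
# normal life expectancy (NLT), i.e. the exposure time at which the lethal
# concentration has fallen to zero. a = -1/d where d is the toxicity
# constant: the reduction in log-scale life expectancy per unit concentration.

new_rle_fit <- function(fit, species, toxicant, screen_flags, method = "single_fit") {
  structure(list(fit = fit, species = species, toxicant = toxicant,
                 screen_flags = screen_flags, method = method),
            class = "rle_fit")
}

#' Fit the RLE model to a toxicity series
#'
#' Ordinary least squares of LC50 (ug/L) on ln(LT50) (ln days). The fit is
#' never silently discarded: screening outcomes are recorded as flags that
#' downstream NLT operations act on. Flags: `low_r2` (R-squared below
#' `r2_threshold`, default 0.8 — the relationship is not considered linear),
#' `nonneg_slope` (no toxicity trend with time), `constant_lc50` (LC50 does
#' not change with exposure time; such series are excluded from NLT work).
#'
#' @param series a [toxicity_series()] with at least 2 records.
#' @param r2_threshold R-squared below which the `low_r2` flag is set.
#' @return an object of class `"rle_fit"`: list with `fit` (a
#'   [fit_ols()] `linear_fit`), `species`, `toxicant`, `screen_flags`
#'   (character vector), `method`.
#' @examples
#' s <- toxicity_series("sp", "tox", c(1, 2, 4), 300 - 100 * log(c(1, 2, 4)))
#' fit_rle(s)  # slope -100, intercept 300, R-squared 1
#' @export
fit_rle <- function(series, r2_threshold = 0.8) {
  stopifnot(inherits(series, "toxicity_series"))
  rec <- series$records
  if (nrow(rec) < 2L)
    rle_stop("at least 2 records with distinct times are required",
             "insufficient_data")
  fit <- fit_ols(log(rec$time_days), rec$lc50_ugL)
  flags <- character(0)
  if (fit$degenerate) flags <- c(flags, "constant_lc50")
  if (fit$r_squared < r2_threshold) flags <- c(flags, "low_r2")
  if (fit$slope_a >= 0) flags <- c(flags, "nonneg_slope")
  new_rle_fit(fit, series$species, series$toxicant, flags)
}

#' Build an RLE fit from published coefficients
#'
#' Wraps an already-published (slope, intercept) pair — e.g. a row of
#' [load_table1_fixture()] — as an `rle_fit` so prediction and NLT operations
#' can be applied without the underlying LC50 series.
#'
#' @param slope_a slope in ug/L per ln(day).
#' @param intercept_b intercept in ug/L.
#' @param species,toxicant identity strings.
#' @param r_squared optional published R-squared (used only for the `low_r2`
#'   flag).
#' @param n_points optional number of points behind the published fit.
#' @param r2_threshold threshold for the `low_r2` flag.
#' @return an object of class `"rle_fit"`.
#' @export
rle_fit_from_coeffs <- function(slope_a, intercept_b, species = "unknown",
                                toxicant = "unknown", r_squared = NA_real_,
                                n_points = NA_integer_, r2_threshold = 0.8) {
  if (!is.finite(slope_a) || !is.finite(intercept_b))
    rle_stop("coefficients must be finite", "bad_input")
  fit <- structure(list(
    slope_a = slope_a, intercept_b = intercept_b,
    r_squared = r_squared, n_points = n_points,
    se_slope = NA_real_, se_intercept = NA_real_,
    degenerate = FALSE
  ), class = "linear_fit")
  flags <- character(0)
  if (!is.na(r_squared) && r_squared < r2_threshold) flags <- c(flags, "low_r2")
  if (slope_a >= 0) flags <- c(flags, "nonneg_slope")
  new_rle_fit(fit, species, toxicant, flags, method = "coefficients")
}

#' @export
print.rle_fit <- function(x, ...) {
  cat(sprintf("RLE fit: %s / %s\n", x$species, x$toxicant))
  cat(sprintf("  LC50 = %.6g ln(LT50) + %.6g   (R-squared %s, n %s)\n",
              x$fit$slope_a, x$fit$intercept_b,
              ifelse(is.na(x$fit$r_squared), "NA", sprintf("%.4f", x$fit$r_squared)),
              ifelse(is.na(x$fit$n_points), "NA", x$fit$n_points)))
  if (length(x$screen_flags))
    cat("  flags:", paste(x$screen_flags, collapse = ", "), "\n")
  if (x$fit$slope_a < 0 && x$fit$intercept_b > 0)
    cat(sprintf("  ln NLT = %.4g  (NLT %.4g days)\n",
                -x$fit$intercept_b / x$fit$slope_a,
                exp(-x$fit$intercept_b / x$fit$slope_a)))
  invisible(x)
}

.check_toxic_trend <- function(fit) {
  if (fit$fit$slope_a >= 0)
    rle_stop("slope is non-negative: no toxicity trend with exposure time",
             "no_toxicity_trend")
}

#' Normal life expectancy from an RLE fit
#'
#' Extrapolates the fitted line to LC50 = 0: ln NLT = -b/a (positive because
#' a < 0 and b > 0), NLT = exp(-b/a) days. This is the exposure time at which
#' the concentration needed to halve the cohort vanishes — the life
#' expectancy in a toxicant-free medium.
#'
#' @param fit an [rle_fit] with negative slope and positive intercept.
#' @return an object of class `"nlt_estimate"`: list with `ln_nlt`,
#'   `nlt_days`, `method`, `n_datasets`.
#' @examples
#' f <- rle_fit_from_coeffs(-9400, 100000)
#' ln_nlt_from_fit(f)$ln_nlt  # 10.638...
#' @export
ln_nlt_from_fit <- function(fit) {
  stopifnot(inherits(fit, "rle_fit"))
  .check_toxic_trend(fit)
  if (fit$fit$intercept_b <= 0)
    rle_stop("intercept is non-positive: NLT extrapolation undefined",
             "negative_extrapolation")
  ln_nlt <- -fit$fit$intercept_b / fit$fit$slope_a
  structure(list(ln_nlt = ln_nlt, nlt_days = exp(ln_nlt),
                 method = fit$method, n_datasets = 1L),
            class = "nlt_estimate")
}

#' @export
print.nlt_estimate <- function(x, ...) {
  cat(sprintf("NLT estimate (%s%s): ln NLT = %.4f, NLT = %.4g days\n",
              x$method,
              if (x$n_datasets > 1L) sprintf(", %d datasets", x$n_datasets) else "",
              x$ln_nlt, x$nlt_days))
  invisible(x)
}

#' Toxicity constant d
#'
#' d = -1/a: the reduction in ln-scale life expectancy per unit toxicant
#' concentration (ln(day) per ug/L). Larger d means a more potent toxicant.
#'
#' @param fit an [rle_fit] with negative slope.
#' @return list of class `"toxicity_constant"` with element `d_value`.
#' @export
toxicity_constant <- function(fit) {
  stopifnot(inherits(fit, "rle_fit"))
  .check_toxic_trend(fit)
  structure(list(d_value = -1 / fit$fit$slope_a), class = "toxicity_constant")
}

#' Predict LC50 at an exposure time
#'
#' Evaluates a ln(t) + b. Beyond the NLT the line is negative, which is
#' unphysical; the prediction is floored at 0 and marked in the
#' `beyond_nlt` attribute (the regression line is truncated at the x-axis).
#'
#' @param fit an [rle_fit].
#' @param t_days positive exposure time(s), days.
#' @return numeric vector of LC50 in ug/L with logical attribute
#'   `beyond_nlt`.
#' @examples
#' f <- rle_fit_from_coeffs(-5800, 36000)
#' predict_lc50(f, 4)  # 36000 - 5800 * log(4)
#' @export
predict_lc50 <- function(fit, t_days) {
  stopifnot(inherits(fit, "rle_fit"))
  t_days <- as.numeric(t_days)
  if (any(!is.finite(t_days) | t_days <= 0))
    rle_stop("exposure times must be positive and finite", "bad_input")
  raw <- fit$fit$slope_a * log(t_days) + fit$fit$intercept_b
  beyond <- raw < 0
  out <- pmax(raw, 0)
  attr(out, "beyond_nlt") <- beyond
  out
}

#' Predict LT50 (reduced life expectancy) at a concentration
#'
#' Inverts the RLE line: LT50 = exp((c - b)/a). At concentration 0 this is
#' exactly the NLT (fraction 1); the fraction of normal life expectancy
#' remaining is LT50/NLT.
#'
#' @param fit an [rle_fit] with negative slope.
#' @param conc_ugL non-negative concentration(s), ug/L.
#' @return a data.frame of class `"rle_prediction"` with columns
#'   `concentration_ugL`, `lt50_days`, `fraction_of_nlt`.
#' @examples
#' f <- rle_fit_from_coeffs(-5800, 36000)
#' predict_lt50(f, 0)$lt50_days  # exp(36000/5800), the NLT
#' @export
predict_lt50 <- function(fit, conc_ugL) {
  stopifnot(inherits(fit, "rle_fit"))
  .check_toxic_trend(fit)
  conc_ugL <- as.numeric(conc_ugL)
  if (any(!is.finite(conc_ugL) | conc_ugL < 0))
    rle_stop("concentrations must be non-negative and finite", "bad_input")
  a <- fit$fit$slope_a; b <- fit$fit$intercept_b
  lt50 <- exp((conc_ugL - b) / a)
  nlt <- exp(-b / a)
  out <- data.frame(concentration_ugL = conc_ugL, lt50_days = lt50,
                    fraction_of_nlt = lt50 / nlt)
  class(out) <- c("rle_prediction", "data.frame")
  out
}

#' Two-point RLE fit from a single endpoint and the reported NLT
#'
#' When only one endpoint (typically the 96-hr LC50) is available, the RLE
#' line can still be drawn: through (ln t, LC50) and the limiting point
#' (ln NLT, 0), using the literature-reported normal life expectancy as the
#' second, toxicity-independent data point. The line interpolates both anchors
#' exactly: a = -LC50 / (ln NLT - ln t), b = -a ln NLT.
#'
#' @param lc50_ugL the endpoint concentration (> 0, ug/L).
#' @param t_days its exposure time (days, 0 < t_days < nlt_days).
#' @param nlt_days the reported normal life expectancy (days).
#' @param species,toxicant identity strings.
#' @return an [rle_fit] with `method = "two_point"` (R-squared 1 by
#'   construction).
#' @examples
#' two_point_fit(100, 4, 4 * exp(2))  # a = -50
#' @export
two_point_fit <- function(lc50_ugL, t_days, nlt_days,
                          species = "unknown", toxicant = "unknown") {
  if (!is.finite(lc50_ugL) || lc50_ugL <= 0)
    rle_stop("'lc50_ugL' must be positive", "bad_input")
  if (!is.finite(t_days) || t_days <= 0)
    rle_stop("'t_days' must be positive", "bad_input")
  if (!is.finite(nlt_days) || nlt_days <= t_days)
    rle_stop("'nlt_days' must exceed 't_days': endpoint lies at or beyond the stated life expectancy",
             "inconsistent_inputs")
  a <- -lc50_ugL / (log(nlt_days) - log(t_days))
  b <- -a * log(nlt_days)
  fit <- structure(list(
    slope_a = a, intercept_b = b, r_squared = 1, n_points = 2L,
    se_slope = NA_real_, se_intercept = NA_real_, degenerate = FALSE
  ), class = "linear_fit")
  new_rle_fit(fit, species, toxicant, character(0), method = "two_point")
}

#' Species-level calculated NLT by averaging dataset estimates
#'
#' Each dataset for a species yields its own ln NLT = -b/a; the species-level
#' calculated NLT is the arithmetic mean of these on the ln scale,
#' exponentiated. At least `min_datasets` datasets (default 4) are required —
#' species with fewer do not get a calculated NLT. Fits flagged
#' `nonneg_slope` or `constant_lc50` are excluded; low-R-squared fits are
#' included unless `r2_min` is given.
#'
#' @param fits a list of [rle_fit] objects, all for the same species.
#' @param r2_min optional minimum R-squared; datasets below it are dropped
#'   before averaging.
#' @param min_datasets minimum number of usable datasets (default 4).
#' @return an `"nlt_estimate"` with `method = "species_average"` and
#'   `n_datasets` the number averaged.
#' @export
species_calculated_nlt <- function(fits, r2_min = NULL, min_datasets = 4L) {
  if (inherits(fits, "rle_fit")) fits <- list(fits)
  if (!length(fits)) rle_stop("no fits supplied", "insufficient_datasets")
  stopifnot(all(vapply(fits, inherits, logical(1), "rle_fit")))
  sp <- unique(vapply(fits, `[[`, character(1), "species"))
  if (length(sp) != 1L)
    rle_stop(sprintf("fits span multiple species: %s", paste(sp, collapse = ", ")),
             "bad_input")
  usable <- vapply(fits, function(f) {
    !any(c("nonneg_slope", "constant_lc50") %in% f$screen_flags) &&
      (is.null(r2_min) || (!is.na(f$fit$r_squared) && f$fit$r_squared >= r2_min))
  }, logical(1))
  fits <- fits[usable]
  if (length(fits) < min_datasets)
    rle_stop(sprintf("species '%s' has %d usable dataset(s); %d required for a calculated NLT",
                     sp, length(fits), min_datasets),
             "insufficient_datasets")
  ln_vals <- vapply(fits, function(f) ln_nlt_from_fit(f)$ln_nlt, numeric(1))
  structure(list(ln_nlt = mean(ln_vals), nlt_days = exp(mean(ln_vals)),
                 method = "species_average", n_datasets = length(fits)),
            class = "nlt_estimate")
}

#' Internal lethal concentration from an ambient one
#'
#' ILC50 = K_B x LC50, where K_B is the equilibrium bioconcentration factor
#' (ratio of organism-internal to ambient-water concentration). Because the
#' conversion is a positive rescaling of the concentration axis, it changes a
#' and b by the same factor and leaves ln NLT untouched: the ambient-water
#' formulation of the model gives the same life-expectancy extrapolation as
#' the internal-concentration one.
#'
#' @param lc50_ugL ambient concentration(s), ug/L, >= 0.
#' @param k_b bioconcentration factor, > 0.
#' @return internal concentration(s).
#' @export
internal_from_ambient <- function(lc50_ugL, k_b) {
  if (!is.finite(k_b) || k_b <= 0)
    rle_stop("'k_b' must be a positive bioconcentration factor", "bad_input")
  lc50_ugL <- as.numeric(lc50_ugL)
  if (any(!is.finite(lc50_ugL) | lc50_ugL < 0))
    rle_stop("concentrations must be non-negative and finite", "bad_input")
  k_b * lc50_ugL
}

#' Through-origin comparison of reported with calculated NLT
#'
#' Regresses the literature-reported NLT on the model-calculated NLT through
#' the origin, on both the day scale and the ln(day) scale (conventions in
#' the literature differ, and the two scales weight large-NLT species very
#' differently; both are therefore reported).
#'
#' @param calculated_nlt_days,reported_nlt_days numeric vectors of species
#'   NLTs, days (at least 2 species).
#' @return list with elements `day` and `ln`, each an
#'   [fit_through_origin()] `origin_fit`.
#' @export
compare_reported_vs_calculated <- function(calculated_nlt_days, reported_nlt_days) {
  x <- as.numeric(calculated_nlt_days); y <- as.numeric(reported_nlt_days)
  if (length(x) != length(y)) rle_stop("lengths differ", "bad_input")
  if (length(x) < 2L)
    rle_stop("at least 2 species pairs are required", "insufficient_data")
  if (any(!is.finite(x) | x <= 0) || any(!is.finite(y) | y <= 0))
    rle_stop("NLTs must be positive", "bad_input")
  list(day = fit_through_origin(x, y),
       ln = fit_through_origin(log(x), log(y)))
}

#' Tabulate RLE fits
#'
#' Serializes a list of [rle_fit] objects to a data.frame with one row per
#' dataset: identity, coefficients, R-squared, flags and — where defined —
#' ln NLT and NLT in days.
#'
#' @param fits list of [rle_fit] objects.
#' @return a data.frame.
#' @export
rle_fit_table <- function(fits) {
  if (inherits(fits, "rle_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    ok <- f$fit$slope_a < 0 && f$fit$intercept_b > 0
    ln_nlt <- if (ok) -f$fit$intercept_b / f$fit$slope_a else NA_real_
    data.frame(
      species = f$species, toxicant = f$toxicant,
      intercept_b_ugL = f$fit$intercept_b, slope_a = f$fit$slope_a,
      r_squared = f$fit$r_squared, n_points = f$fit$n_points,
      ln_nlt = ln_nlt, nlt_days = if (ok) exp(ln_nlt) else NA_real_,
      method = f$method,
      flags = paste(f$screen_flags, collapse = ";")
    )
  })
  do.call(rbind, rows)
}

#' Species-level NLT table
#'
#' Applies [species_calculated_nlt()] to every species in a list of fits and
#' tabulates those species that meet the dataset minimum; the others are
#' reported with NA estimates and the reason.
#'
#' @inheritParams species_calculated_nlt
#' @param fits list of [rle_fit] objects (any mix of species).
#' @return a data.frame with one row per species: `species`, `n_datasets`,
#'   `ln_nlt`, `nlt_days`, `status`.
#' @export
species_nlt_table <- function(fits, r2_min = NULL, min_datasets = 4L) {
  sp <- vapply(fits, `[[`, character(1), "species")
  rows <- lapply(unique(sp), function(s) {
    est <- tryCatch(
      species_calculated_nlt(fits[sp == s], r2_min = r2_min,
                             min_datasets = min_datasets),
      rletox_insufficient_datasets = function(e) e)
    if (inherits(est, "nlt_estimate")) {
      data.frame(species = s, n_datasets = est$n_datasets,
                 ln_nlt = est$ln_nlt, nlt_days = est$nlt_days, status = "ok")
    } else {
      data.frame(species = s, n_datasets = sum(sp == s),
                 ln_nlt = NA_real_, nlt_days = NA_real_,
                 status = "insufficient_datasets")
    }
  })
  do.call(rbind, rows)
}
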