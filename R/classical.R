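# Contrast models: Haber's rule (C x t = k) and Warren's threshold equation
# ((C - C0) x t = k). Both predict time diverging as concentration falls to
# the asymptote (0 or C0), unlike the RLE model's finite NLT.

#' Fit Haber's rule to a toxicity series
#'
#' Haber's rule posits a constant concentration-time product C x t = k for a
#' fixed effect. k is estimated as the geometric mean of the observed
#' products (equivalently, least squares on the log scale with the slope of
#' ln C on ln t fixed at -1): symmetric in c and t and exact on ideal data.
#' An arithmetic-mean estimator is available as an option.
#'
#' @param series a [toxicity_series()]; all LC50 values must be positive.
#' @param method `"geometric"` (default) or `"arithmetic"` mean of the
#'   products.
#' @return list of class `"haber_fit"` with `k_value` (ug day / L),
#'   `method`, `n_points`.
#' @export
fit_haber <- function(series, method = c("geometric", "arithmetic")) {
  stopifnot(inherits(series, "toxicity_series"))
  method <- match.arg(method)
  rec <- series$records
  if (any(rec$lc50_ugL <= 0))
    rle_stop("Haber's rule requires strictly positive concentrations",
             "bad_input")
  prod <- rec$lc50_ugL * rec$time_days
  k <- if (method == "geometric") exp(mean(log(prod))) else mean(prod)
  structure(list(k_value = k, method = method, n_points = nrow(rec)),
            class = "haber_fit")
}

#' @export
print.haber_fit <- function(x, ...) {
  cat(sprintf("Haber fit (n = %d, %s mean): C x t = %.6g ug day/L\n",
              x$n_points, x$method, x$k_value))
  invisible(x)
}

#' Fit Warren's threshold equation to a toxicity series
#'
#' Warren's equation (C - C0) x t = k adds a no-effect threshold C0 below
#' which toxicity is never reached. Fitted by least squares on the
#' concentration scale, c_i ~ C0 + k/t_i, with C0 constrained to
#' [0, min(c)): for fixed C0 the optimal k is closed-form, and C0 is located
#' by a coarse grid followed by golden-section/parabolic refinement
#' (tolerance 1e-8). With C0 = 0 the model reduces to Haber's rule.
#'
#' @param series a [toxicity_series()] with at least 3 records (two free
#'   parameters).
#' @return list of class `"warren_fit"` with `c0` (ug/L), `k_value`
#'   (ug day / L), `rss` (residual sum of squares on the concentration
#'   scale), `n_points`.
#' @export
fit_warren <- function(series) {
  stopifnot(inherits(series, "toxicity_series"))
  rec <- series$records
  if (nrow(rec) < 3L)
    rle_stop("Warren's equation has two parameters; at least 3 records are required",
             "insufficient_data")
  cc <- rec$lc50_ugL; tt <- rec$time_days
  w <- 1 / tt                       # model: c = c0 + k * (1/t)
  k_given_c0 <- function(c0) sum((cc - c0) * w) / sum(w^2)
  rss_given_c0 <- function(c0) {
    k <- max(k_given_c0(c0), 0)     # negative k is unphysical
    sum((cc - c0 - k * w)^2)
  }
  upper <- min(cc) * (1 - 1e-12)
  if (upper <= 0) {                  # some concentration at zero: threshold 0
    c0_hat <- 0
  } else {
    grid <- seq(0, upper, length.out = 201L)
    r <- vapply(grid, rss_given_c0, numeric(1))
    i <- which.min(r)
    lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
    c0_hat <- if (lo < hi) {
      stats::optimize(rss_given_c0, c(lo, hi), tol = 1e-8)$minimum
    } else lo
    # the boundary c0 = 0 (the Haber limit) is not interior to optimize()'s
    # bracket; keep it if it is at least as good
    if (rss_given_c0(0) <= rss_given_c0(c0_hat)) c0_hat <- 0
  }
  k_hat <- max(k_given_c0(c0_hat), 0)
  structure(list(c0 = c0_hat, k_value = k_hat,
                 rss = sum((cc - c0_hat - k_hat * w)^2), n_points = nrow(rec)),
            class = "warren_fit")
}

#' @export
print.warren_fit <- function(x, ...) {
  cat(sprintf("Warren fit (n = %d): (C - %.6g) x t = %.6g, RSS = %.4g\n",
              x$n_points, x$c0, x$k_value, x$rss))
  invisible(x)
}

#' Predict lethal time from a classical model
#'
#' Haber: t = k/c; Warren: t = k/(c - C0). Both diverge at the model's
#' asymptote (c = 0, respectively c = C0), so concentrations at or below it
#' are a divergence error — the contrast with the RLE model, whose time at
#' zero concentration is the finite NLT.
#'
#' @param model a `"haber_fit"` or `"warren_fit"`.
#' @param conc_ugL concentration(s) above the model's asymptote.
#' @return predicted time(s) in days.
#' @export
predict_time <- function(model, conc_ugL) UseMethod("predict_time")

#' @export
predict_time.haber_fit <- function(model, conc_ugL) {
  conc_ugL <- as.numeric(conc_ugL)
  if (any(!is.finite(conc_ugL) | conc_ugL <= 0))
    rle_stop("Haber's rule diverges at its asymptote, concentration 0; concentrations must be > 0",
             "divergence")
  model$k_value / conc_ugL
}

#' @export
predict_time.warren_fit <- function(model, conc_ugL) {
  conc_ugL <- as.numeric(conc_ugL)
  if (any(!is.finite(conc_ugL) | conc_ugL <= model$c0))
    rle_stop(sprintf("Warren's equation diverges at its asymptote, the threshold C0 = %g ug/L; concentrations must exceed it",
                     model$c0), "divergence")
  model$k_value / (conc_ugL - model$c0)
}

#' Compare RLE, Haber and Warren fits on one series
#'
#' Fits all three models to the same series and reports residual sums of
#' squares on the concentration scale, plus an R-squared analogue
#' 1 - RSS/SStot (SStot centred). Raw RSS is the headline figure: with the
#' typical 4-point series, information-criterion comparisons would overreach.
#'
#' @param series a [toxicity_series()] satisfying all three models'
#'   preconditions (>= 3 records, positive concentrations).
#' @return a data.frame with one row per model: `model`, `rss`,
#'   `r2_analogue`, and parameter columns (`slope_a`, `intercept_b`,
#'   `k_value`, `c0`; NA where not applicable).
#' @export
compare_models <- function(series) {
  stopifnot(inherits(series, "toxicity_series"))
  rec <- series$records
  rle <- fit_rle(series)
  hab <- fit_haber(series)
  war <- fit_warren(series)
  pred_rle <- rle$fit$slope_a * log(rec$time_days) + rle$fit$intercept_b
  rss <- c(
    RLE = sum((rec$lc50_ugL - pred_rle)^2),
    Haber = sum((rec$lc50_ugL - hab$k_value / rec$time_days)^2),
    Warren = war$rss
  )
  sstot <- sum((rec$lc50_ugL - mean(rec$lc50_ugL))^2)
  data.frame(
    model = names(rss), rss = unname(rss),
    r2_analogue = if (sstot > 0) 1 - unname(rss) / sstot else NA_real_,
    slope_a = c(rle$fit$slope_a, NA, NA),
    intercept_b = c(rle$fit$intercept_b, NA, NA),
    k_value = c(NA, hab$k_value, war$k_value),
    c0 = c(NA, NA, war$c0)
  )
}
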