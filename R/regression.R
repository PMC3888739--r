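# Least-squares primitives: ordinary and through-origin fits.

#' Ordinary least squares of y on x
#'
#' Plain unweighted OLS, as used to regress LC50 on ln LT50. R-squared is the
#' coefficient of determination, 1 - SSres/SStot. When the response is
#' constant (SStot = 0) the fit is flagged degenerate and R-squared is
#' reported as 0 rather than NaN; the degenerate flag is what drives the
#' screen that excludes series whose LC50 does not change with exposure time.
#'
#' @param x,y numeric vectors of equal length (at least 2 points; x not all
#'   identical).
#' @return an object of class `"linear_fit"`: list with `slope_a`,
#'   `intercept_b`, `r_squared`, `n_points`, `se_slope`, `se_intercept`,
#'   `degenerate`.
#' @examples
#' fit_ols(log(c(1, 2, 4)), c(300, 230.69, 161.37))
#' @export
fit_ols <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) rle_stop("'x' and 'y' lengths differ", "bad_input")
  if (length(x) < 2L) rle_stop("at least 2 points are required", "insufficient_data")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    rle_stop("points must be finite", "bad_input")
  if (diff(range(x)) == 0)
    rle_stop("all x values identical: design is degenerate", "degenerate_design")

  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  sstot <- sum((y - mean(y))^2)
  ssres <- sum(stats::residuals(fit)^2)
  degenerate <- sstot == 0
  r2 <- if (degenerate) 0 else 1 - ssres / sstot
  n <- length(x)
  se <- if (n > 2L) {
    s2 <- ssres / (n - 2)
    sxx <- sum((x - mean(x))^2)
    c(sqrt(s2 * (1 / n + mean(x)^2 / sxx)), sqrt(s2 / sxx))
  } else c(NA_real_, NA_real_)  # saturated: no residual df
  structure(list(
    slope_a = unname(cf[2]), intercept_b = unname(cf[1]),
    r_squared = min(max(r2, 0), 1), n_points = length(x),
    se_slope = unname(se[2]), se_intercept = unname(se[1]),
    degenerate = degenerate
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d): y = %.6g x + %.6g, R-squared = %.4f%s\n",
              x$n_points, x$slope_a, x$intercept_b, x$r_squared,
              if (x$degenerate) " [degenerate: constant response]" else ""))
  invisible(x)
}

#' Least squares through the origin
#'
#' Fits y = slope * x with no intercept; slope = sum(xy)/sum(x^2). The
#' R-squared is computed against the uncentred total sum of squares, the
#' standard convention for no-intercept models (it is not comparable to the
#' centred R-squared of [fit_ols()]).
#'
#' @param x,y numeric vectors of equal length (at least 2 points; x not all
#'   zero).
#' @return an object of class `"origin_fit"`: list with `slope`, `r_squared`,
#'   `n_points`.
#' @examples
#' fit_through_origin(c(1, 2, 3), c(2, 4, 6))  # slope 2
#' @export
fit_through_origin <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) rle_stop("'x' and 'y' lengths differ", "bad_input")
  if (length(x) < 2L) rle_stop("at least 2 points are required", "insufficient_data")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    rle_stop("points must be finite", "bad_input")
  if (all(x == 0))
    rle_stop("all x values zero: design is degenerate", "degenerate_design")
  slope <- sum(x * y) / sum(x^2)
  ssres <- sum((y - slope * x)^2)
  sstot <- sum(y^2)  # uncentred
  r2 <- if (sstot == 0) 0 else 1 - ssres / sstot
  structure(list(slope = slope, r_squared = min(max(r2, 0), 1),
                 n_points = length(x)),
            class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf("Through-origin fit (n = %d): y = %.6g x, uncentred R-squared = %.4f\n",
              x$n_points, x$slope, x$r_squared))
  invisible(x)
}
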