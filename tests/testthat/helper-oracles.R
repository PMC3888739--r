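# Independent oracles and small builders shared across test files.

# closed-form normal equations, independent of the fitting code under test
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  a <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  b <- (sy - a * sx) / n
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sum((y - a * x - b)^2) / sstot else 0
  list(slope = a, intercept = b, r_squared = r2)
}

origin_oracle <- function(x, y) sum(x * y) / sum(x^2)

# exact-line RLE series: LC50 = a ln(t) + b
make_rle_series <- function(a = -100, b = 300, times = c(1, 2, 4),
                            species = "sp", toxicant = "tox", ...) {
  toxicity_series(species, toxicant, times, a * log(times) + b, ...)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
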