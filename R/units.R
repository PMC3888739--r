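# Unit canonicalization: all concentrations in ug/L, all times in days.

# structured conditions so callers/tests can distinguish failure modes
rle_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("rletox_", class), "rletox_error"),
                      call = call))
}

.conc_factor <- c(
  "ug/l" = 1, "µg/l" = 1, "μg/l" = 1, "ppb" = 1,
  "mg/l" = 1e3, "ppm" = 1e3,
  "g/l"  = 1e6
)

.time_factor <- c(
  "seconds" = 1 / 86400, "second" = 1 / 86400, "sec" = 1 / 86400, "s" = 1 / 86400,
  "minutes" = 1 / 1440, "minute" = 1 / 1440, "min" = 1 / 1440,
  "hours" = 1 / 24, "hour" = 1 / 24, "hrs" = 1 / 24, "hr" = 1 / 24, "h" = 1 / 24,
  "days" = 1, "day" = 1, "d" = 1
)

#' Convert a concentration to micrograms per litre
#'
#' Canonicalizes aqueous toxicant concentrations to ug/L. `ppm` and `ppb` are
#' taken as mg/L and ug/L equivalents, which assumes a dilute aqueous solution
#' of density 1 g/mL; this is appropriate for ambient-water toxicity data and
#' is not configurable.
#'
#' @param value numeric vector of non-negative concentrations.
#' @param unit character vector (recycled) naming the unit of each value; one
#'   of `"ug/L"` (also accepted with a micro sign), `"mg/L"`, `"g/L"`,
#'   `"ppm"`, `"ppb"`. Case-insensitive.
#' @return numeric vector of concentrations in ug/L.
#' @examples
#' normalize_concentration(1, "mg/L")    # 1000
#' normalize_concentration(c(5, 2), c("g/L", "ppb"))
#' @export
normalize_concentration <- function(value, unit) {
  if (!is.numeric(value)) rle_stop("'value' must be numeric", "bad_input")
  key <- tolower(trimws(as.character(unit)))
  bad <- !(key %in% names(.conc_factor))
  if (any(bad)) {
    rle_stop(sprintf("unknown concentration unit: %s",
                     paste(sQuote(unique(unit[bad])), collapse = ", ")),
             "unknown_unit")
  }
  if (any(is.finite(value) & value < 0)) {
    rle_stop("concentrations must be non-negative", "bad_input")
  }
  unname(value * .conc_factor[rep_len(key, length(value))])
}

#' Convert an exposure duration to days
#'
#' @param value numeric vector of positive durations.
#' @param unit character vector (recycled): `"seconds"`, `"minutes"`,
#'   `"hours"` or `"days"` (common abbreviations accepted, case-insensitive).
#' @return numeric vector of durations in days.
#' @examples
#' normalize_time(96, "hours")  # 4
#' @export
normalize_time <- function(value, unit) {
  if (!is.numeric(value)) rle_stop("'value' must be numeric", "bad_input")
  key <- tolower(trimws(as.character(unit)))
  bad <- !(key %in% names(.time_factor))
  if (any(bad)) {
    rle_stop(sprintf("unknown time unit: %s",
                     paste(sQuote(unique(unit[bad])), collapse = ", ")),
             "unknown_unit")
  }
  if (any(!is.finite(value) | value <= 0)) {
    rle_stop("exposure times must be positive and finite", "bad_input")
  }
  unname(value * .time_factor[rep_len(key, length(value))])
}
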