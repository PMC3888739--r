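# Packaged table of published fish LC50-vs-ln(LT50) regression coefficients.

#' Load the packaged table of published fish regression coefficients
#'
#' Returns the packaged compilation of literature regressions of LC50 (ug/L)
#' on ln LT50 (days) for fish exposed to organic toxicants: 67
#' coefficient-bearing datasets across 16 species. Each row carries the
#' species, toxicant, intercept `b` (ug/L), slope `a` (ug/L per ln day, all
#' negative), the regression R-squared, the literature-reported normal life
#' expectancy of the species (days), and — for the 10 species with at least
#' four datasets — the published species-average calculated ln NLT.
#'
#' Two further datasets in the source compilation print no coefficients and
#' are therefore not included; `load_table1_omissions()` lists them. One
#' intercept (Anguilla anguilla, methylparathion) is typographically ambiguous
#' in the source ("54,00") and is shipped as 5400 with the flag
#' `ambiguous_intercept`.
#'
#' @return a data.frame with columns `species`, `toxicant`, `dataset`,
#'   `intercept_b_ugL`, `slope_a`, `r_squared`, `reported_nlt_days`,
#'   `reported_calculated_ln_nlt`, `flag`, `source_ref`.
#' @examples
#' tab <- load_table1_fixture()
#' nrow(tab)                      # 67
#' sum(tab$r_squared < 0.8)       # 3
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1.csv", package = "rletox", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname load_table1_fixture
#' @export
load_table1_omissions <- function() {
  path <- system.file("extdata", "table1_omitted.csv", package = "rletox",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Convert fixture rows to RLE fits
#'
#' Builds one coefficient-only [rle_fit] per fixture row so that NLT
#' extrapolation and species averaging can be applied to the published
#' coefficients directly (the underlying LC50 series are not published).
#'
#' @param entries a data.frame as returned by [load_table1_fixture()], or a
#'   subset of its rows.
#' @param r2_threshold threshold below which the `low_r2` screen flag is set.
#' @return a list of [rle_fit] objects.
#' @export
fixture_fits <- function(entries, r2_threshold = 0.8) {
  lapply(seq_len(nrow(entries)), function(i) {
    rle_fit_from_coeffs(
      slope_a = entries$slope_a[i], intercept_b = entries$intercept_b_ugL[i],
      species = entries$species[i], toxicant = entries$toxicant[i],
      r_squared = entries$r_squared[i], r2_threshold = r2_threshold
    )
  })
}
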