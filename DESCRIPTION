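Package: rletox
Title: Reduced Life Expectancy Modelling of Lethal Toxicity Under Long-Term Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the reduced life expectancy (RLE) model for lethal toxicity
    of aquatic organisms under long-term exposure, in which the median lethal
    concentration (LC50) declines linearly with the natural logarithm of the
    median lethal time (LT50) and the regression line's x-intercept is the
    species' normal life expectancy (NLT). Provides unit canonicalization and
    CSV ingest of toxicity series, ordinary and through-origin least squares,
    NLT extrapolation and species-level averaging, predictions of toxicity at
    arbitrary exposure times and of life-expectancy reduction at arbitrary
    concentrations, a two-point method for single-endpoint data, Haber's rule
    and Warren's threshold equation as contrast models, a packaged table of
    published fish regression coefficients, and a synthetic-data generator
    for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
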