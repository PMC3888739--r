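---
title: "The reduced life expectancy model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The reduced life expectancy model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rletox)
```

## The model

Classical concentration–time toxicology descends from Haber's rule,
$C \times t = k$: a fixed concentration–time product produces a fixed
effect. Its corollary is awkward at low dose — as $C \to 0$ the time to
effect diverges, so an organism in clean water "never dies". Warren's
variant $(C - C_0)\,t = k$ moves the divergence to a threshold
concentration $C_0$ but keeps it.

The reduced life expectancy (RLE) model replaces divergence with a finite
anchor. For a cohort exposed to a constant concentration, let
$\mathrm{LC}_{50}$ be the concentration lethal to half the cohort at
exposure duration $\mathrm{LT}_{50}$. The model is the linear relation

$$\mathrm{LC}_{50} = a \ln(\mathrm{LT}_{50}) + b, \qquad a < 0,$$

equivalently $\mathrm{LC}_{50} = [\ln(\mathrm{NLT}) - \ln(\mathrm{LT}_{50})]/d$
with toxicity constant $d = -1/a$ (the reduction in ln-scale life expectancy
per unit concentration, ln(day) per µg/L). Setting
$\mathrm{LC}_{50} = 0$ gives the x-intercept

$$\ln(\mathrm{NLT}) = -b/a,$$

the **normal life expectancy**: the time to 50% mortality with no toxicant
at all. Exposure *shortens life expectancy* rather than merely delaying an
effect, and the zero-concentration limit is the species' own lifespan, not
infinity. We use $-b/a$ throughout: with $a<0$ and $b>0$ it is the positive
root, and it is the form consistent with every species value in the
packaged coefficient table (statements of the intercept as $b/a$ elide the
sign of $a = -1/d$).

The same relation holds for internal (body-residue) concentrations: at
equilibrium the bioconcentration factor $K_B$ rescales the concentration
axis ($\mathrm{ILC}_{50} = K_B \cdot \mathrm{LC}_{50}$), multiplying $a$
and $b$ equally and leaving $-b/a$ untouched. Only this static conversion
is implemented; uptake kinetics are out of scope.

## Fitting and screening

`fit_rle()` performs plain unweighted OLS of LC50 (µg/L) on ln LT50
(days), the estimator under which the published coefficient compilations
were produced; no weighting or robust loss is offered. Units are
canonicalized once at ingest (`read_series_csv()`, `normalize_*()`), with
ppm/ppb read as mg/L and µg/L equivalents under the dilute-aqueous-solution
assumption (density 1 g/mL) appropriate to ambient water.

Screening is by flags, never silent exclusion:

* `constant_lc50` — the response does not change with time (total sum of
  squares zero). R² is reported as 0, not NaN, and the flag drives the
  rule that such series contribute no NLT.
* `low_r2` — R² below the linearity threshold, default **0.8**; below it
  the relation is not considered to follow a linear trend.
* `nonneg_slope` — no toxicity trend. The fit is inspectable, but NLT
  operations (`ln_nlt_from_fit()`, `predict_lt50()`, `toxicity_constant()`)
  refuse it.

Species-level NLT (`species_calculated_nlt()`) is the arithmetic mean of
per-dataset $-b/a$ on the ln scale, exponentiated, and requires at least
**4** datasets (configurable via `min_datasets` for simulation studies).
Averaging on the day scale reproduces none of the published species values,
while the ln-scale mean reproduces all of them within the rounding of
2-significant-figure coefficients (≈1–3%); low-R² datasets are included by
default because that choice matches the published species values best, with
`r2_min` exposed for sensitivity analysis. `predict_lc50()` truncates the
line at the x-axis — beyond the NLT it returns 0 with a `beyond_nlt` flag
rather than a negative concentration.

With a single endpoint (typically a 96-hr LC50), `two_point_fit()` draws
the line through that point and the anchor $(\ln \mathrm{NLT}, 0)$, using a
literature life expectancy as a second, toxicity-independent datum. Both
anchors are interpolated exactly.

## The packaged coefficient table

`load_table1_fixture()` ships the published compilation of 67 fish
regressions (16 species, organophosphates, organochlorines, pyrethroids and
antiparasites): intercept $b$ (µg/L), slope $a$ (all negative), R², the
literature-reported NLT, and for the 10 species with ≥4 datasets the
published species-average calculated ln NLT. Exactly 3 datasets fall below
the R² = 0.8 screen. Two source rows print no coefficients and are listed
by `load_table1_omissions()` instead of being guessed; one intercept is
typographically ambiguous in the source ("54,00") and is shipped as 5400
carrying the flag `ambiguous_intercept`. One published worked-example slope
(−5800 for dimethoate/*O. niloticus*) disagrees with the same dataset's
tabulated slope (−7800); the table keeps the tabulated value and the worked
example is exercised with its own printed coefficients.

`compare_reported_vs_calculated()` regresses reported on calculated NLT
through the origin on *both* the day and ln(day) scales and reports both:
the two conventions weight long-lived species very differently, the source
compilations themselves print inconsistent slopes for this comparison
(0.996 vs 0.998), and neither is recoverable from 2-significant-figure
coefficients — so the package computes rather than hard-codes.

## Contrast models

`fit_haber()` estimates $k$ as the geometric mean of the products
$c_i t_i$ — the least-squares solution on the log scale with the slope
fixed at −1, symmetric in $c$ and $t$ and exact on ideal data (arithmetic
mean available as an option). `fit_warren()` fits $c_i \sim C_0 + k/t_i$ by
profiled least squares: $k$ is closed-form given $C_0$, and $C_0$ is
located on $[0, \min c_i)$ by a 201-point grid followed by
`stats::optimize()` refinement to tolerance 1e−8, with the Haber boundary
$C_0 = 0$ retained whenever it fits at least as well — this avoids unstable
joint nonlinear optimization on the typical 4-point series. Neither model
was fitted quantitatively in the source compilation, so their behaviour
here is definitional, validated by nesting (Warren at $C_0=0$ equals
Haber) and by exact-data identities. `compare_models()` reports raw RSS on
the concentration scale; with $n \approx 4$, information criteria would
overreach.

## Synthetic data and what it does (not) show

`generate_series()` emulates the dominant literature design: LC50 recorded
at 24/48/72/96 hr, i.e. times $\{1,2,3,4\}$ days, from a true line with
additive Gaussian noise *on the concentration scale* — the scale the model
is fitted on, so the generator matches the fitted error structure by
construction. Defaults $a=-100$, $b=300$, `noise_sd = 10` µg/L put the
true ln NLT at 3 with noise a few percent of signal. Negative draws are
truncated at 0 and counted (`n_truncated` attribute), so tests can demand
a truncation-free regime; multiplicative lognormal noise is available where
truncation would otherwise bite. One integer seed drives everything, with
the substream for series $i$ derived by counter
(`(seed mod 2147483647) + i`), so series are reproducible individually;
adjacent top-level seeds share substreams, so replicate *studies* should
use well-separated seeds.

What passing recovery tests show: the estimator pipeline is correct
(noiseless data recovered exactly; at the default noise the mean recovered
ln NLT over 200 series sits within Monte-Carlo error of the truth, with
roughly nominal 95% interval coverage). What they do not show: real
toxicity series have heteroscedastic, between-laboratory and
rounding error, correlated determinations at successive times, and
model misfit (the 3/67 low-R² screen exists for a reason) — none of which
the generator emulates. Recovery results are a check on the software and
the estimator, not evidence about field data.

## Numerical choices and degenerate inputs

* OLS via `stats::lm`; standard errors in closed form (saturated 2-point
  fits report NA, with R² = 1 by convention for two distinct points).
* Through-origin slope $\sum xy / \sum x^2$ with **uncentred** R², the
  standard convention for no-intercept models (not comparable with the
  centred R² of ordinary fits).
* Degenerate designs (all x equal; all x zero for the origin fit; fewer
  than 2 points) are structured errors, as are non-positive times, negative
  concentrations, unknown unit tokens, and two-point inputs with the
  endpoint at or beyond the stated life expectancy.
* All comparisons in the test suite at explicit tolerances: the OLS path
  agrees with an independent normal-equations solution to 1e−10 relative
  over 1000 random designs; prediction round-trips hold to 1e−9 relative.

## Problem sizes

The shipped simulation defaults keep every study small enough to be rerun
casually: recovery experiments in the tests use 100–400 series of 4 points,
and the packaged example configuration (`example_sim_config.dcf`) uses 50.
These sizes give Monte-Carlo standard errors an order of magnitude below
the effects being checked.

## Known limitations

* Single-stage model only: series that flatten at long exposure (a
  two-stage regime) are outside scope and will simply fit poorly.
* NLT extrapolation leans on linearity *beyond* the observed 1–4 day
  window; the R² screen checks linearity only inside it.
* Reported NLTs are themselves noisy (husbandry, temperature, geography),
  which bounds how closely calculated and reported values can agree.
* The dilute-solution ppm/ppb equivalence is wrong for dense matrices; the
  package does not attempt density corrections.
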