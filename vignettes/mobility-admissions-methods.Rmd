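---
title: "Methods: community mobility indices and trauma outpatient admissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community mobility indices and trauma outpatient admissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobadmit)
```

## The problem

During the COVID-19 pandemic, governments restricted population movement,
and trauma departments saw admissions fall. Smartphone-derived community
mobility reports (of the kind Google and Apple published during 2020-2021)
offer a daily, population-level measurement of how much people actually
moved. `mobadmit` implements a pipeline that relates these mobility
reports to daily trauma outpatient counts: it builds a leisure-related
composite mobility index, expresses admissions on the providers' own
baseline scales, and quantifies the association by Pearson correlation and
simple linear regression, with lockdown-period summary tables against
matched previous-year intervals.

The intended users are clinical epidemiologists and hospital planners who
have daily admission counts for one or more cities and want a reproducible
answer to "how tightly did admissions track mobility, and how much did each
lockdown suppress them?".

## Indices

**Leisure mobility index.** Google-style reports give, per day and
location category, a percent change from baseline (CFB). The composite
index averages the four categories tied to discretionary movement,

$$MI_L = \tfrac{1}{4}\left[\mathrm{CFB}(rr) + \mathrm{CFB}(pa) +
\mathrm{CFB}(ts) - \mathrm{CFB}(res)\right],$$

with *rr* retail/recreation, *pa* parks, *ts* transit stations and *res*
residential. Residential enters negatively: more time at home indicates
compliance with restrictions. Grocery/pharmacy is excluded as essential
activity, and workplaces because remote work made that category an
unreliable mobility signal. The index is linear and strictly monotone in
each argument; a date missing any of the four categories is left missing
and handled by the imputation stage, keeping the formula a pure
four-argument map.

**Outpatient indices.** To compare counts with mobility on an equal
footing, daily counts are converted to percent change against a baseline
constructed per provider convention:

* *Weekday-median convention* (Google-style): the baseline is the median
  count of each calendar weekday over a reference window, and
  $AOI(d) = 100\,(c_d - b_{w(d)})/b_{w(d)}$. The default reference window
  is 3 January to 6 February 2019 — the mirror, one year earlier, of the
  provider's own 2020 baseline window. Nothing pins the pre-pandemic
  reference to a specific window, so this mirrored window is a design
  choice (configurable via `aoi_reference_window`); it keeps the weekday
  structure and season aligned with the mobility baseline.
* *Single-day convention* (Apple-style): the baseline is the count on one
  reference day, 13 January 2020 by default, matching the provider's
  baseline-indexed volumes (100 = baseline day). Apple-style feeds carry
  several transportation types; their percent changes (`value - 100`) are
  combined by unweighted mean over the types available on a date, a
  neutral choice since no weighting is canonical.

Both indices operate on city totals (female + male); the sex split is kept
for reporting only, because the association analysis is defined on total
daily load.

## Gap imputation

Sporadic missing days are filled by *seasonal-split interpolation*: the
daily series is split into seven weekday subseries, and gaps are linearly
interpolated between the nearest observed values of the *same weekday*.
This preserves the strong weekly cycle of admissions, which plain
interpolation across adjacent days would smear. Leading and trailing gaps,
where interpolation is undefined, take the nearest observation within the
subseries (a deliberate, conservative edge policy). Two properties are
enforced by tests: imputation is idempotent, and every filled value lies
within the observed range of its own weekday subseries. A weekday with no
observation at all is an error, not a guess. The pipeline logs the number
of imputed days per series so gap diagnostics are reproducible.

Imputation is applied to the raw inputs (counts and mobility categories)
*before* index computation; this keeps every index date complete and makes
the downstream sample sizes calendar-determined. Computing indices first
and imputing afterwards is available by disabling imputation and handling
the index series manually, but raw-first is the default because percent
changes of interpolated counts remain interpretable, whereas interpolating
ratios can leave the two analysis stages inconsistent with each other.

## Lockdown summaries

Three Austrian hard lockdowns fall in the study span (16 Mar-30 Apr 2020,
17 Nov-6 Dec 2020, 26 Dec 2020-7 Feb 2021; a second preset starts the
first lockdown on 15 March, the officially announced date — published
sources differ by one day, and neither is declared authoritative). All
intervals are inclusive at both ends. Each period is compared with the
same calendar interval one year earlier; 29 February has no match and is
excluded from both sides of a matched comparison.

The summary statistic is the average number of outpatients per day (AO/d)
in each interval and the percent difference between the two, rounded to
integer percent **half away from zero**. This convention was fixed by
exhaustively checking candidate conventions (half-up, half-away,
truncation, banker's) against published three-city lockdown summaries:
half-away-from-zero reproduces 26 of 27 cells from the printed one-decimal
AO/d values. The remaining cell cannot be reproduced from printed values
under *any* value-faithful rounding — its unrounded inputs sit on the far
side of a rounding boundary — and the published total rows are not exactly
additive in their last printed decimal for the same reason (totals were
computed before rounding). The test suite asserts exactly this state of
affairs rather than smoothing it away.

## Correlation and regression

The association is estimated on **daily pairs** of $(MI_L, AOI)$ per city:
the weekly means the package also produces are for display, while the
inference keeps daily granularity (a year-scale analysis at weekly
granularity would have far too few degrees of freedom to match the
reported precision of such analyses). Estimation is delegated to the
standard machinery — `stats::cor.test()` and `stats::lm()` — behind a thin
contract layer:

* `pearson_corr()` reports r, a two-sided p-value from the t transform of
  r with $n-2$ degrees of freedom, and a Fisher-z confidence interval
  ($z = \operatorname{artanh} r$, SE $1/\sqrt{n-3}$), at a configurable
  $\alpha$ (default 0.05).
* `simple_ols()` reports intercept, slope, $r^2$, adjusted $r^2$, and the
  F statistic on $(1, n-2)$ degrees of freedom. `adj_r2_from_f()` inverts
  the F statistic analytically ($r^2 = F/(F + df_2)$ for one predictor),
  which is how a reported adjusted $r^2$ can be checked against a reported
  F without the underlying data.

An "all cities" result pools the daily pairs of every city into one sample
(default). How a multi-city summary correlation *should* be formed is
genuinely open — pooling pairs, averaging the indices across cities per
day, or averaging coefficients all have precedents — so the per-date
averaging variant is available as `pooling = "average_indices"`. Pooling
pairs is the default because it treats each city-day as one observation of
the same relationship and reproduces the characteristic attenuation of the
pooled Apple-convention correlation (city-specific single-day baselines
shift each city's index by a different offset, which weakens the pooled r
relative to the per-city ones — visible in the synthetic runs below).

Complete-case pairing applies throughout: dates missing in either series
are dropped pairwise (relevant only when imputation is off).

## The synthetic data generator

Hospital admission records are not freely redistributable, so the package
ships a seeded generator that emulates the statistical structure the
analysis assumes, at the scale of the study setting:

| parameter | default | meaning |
|---|---|---|
| cities | Graz 150, Innsbruck 115, Vienna 175 | base mean outpatients/day, near observed 2019 levels |
| span | 2019-01-01 to 2021-02-08 | two pre-pandemic-to-lockdown years |
| weekday profile | 1.05, 0.97, 0.95, 0.95, 1.00, 1.06, 1.02 | multiplicative Mon-Sun admission seasonality (mean 1) |
| lockdown admission drops | 0.62, 0.40, 0.27 | fraction of admissions suppressed per lockdown |
| lockdown mobility drops | 0.47, 0.36, 0.34 | depth of the composite-index dip per lockdown |
| `compliance_decay` | 1 | extra attenuation dividing successive drops; the defaults already fade across lockdowns, so the knob is neutral unless raised |
| `dispersion` | 60 | negative-binomial size; daily counts are overdispersed (real admission counts are), variance $\mu + \mu^2/60$ |
| `latent_sd` | 4 | SD (percentage points) of a shared day effect entering both channels |
| `target_corr` | 0.7 | intended index-index correlation over the Google-era window |
| missing days | 38 Graz, 30 Innsbruck, 0 Vienna | seeded random count gaps per city |

Counts are negative-binomial with mean
`base x weekday factor x (1 - effective drop) x (1 + latent)`, split
binomially into female/male (female share 0.47). Mobility categories
follow the dip profile scaled by fixed category weights (residential with
opposite sign, so staying home rises when the others fall), the Apple-style
types dip deeper (driving reaches about -75% when the index is near -47%),
and the Apple baseline day is exactly 100 by construction of the format.

**Correlation targeting.** The two series already share the deterministic
lockdown dips and the latent day effect, which fixes their covariance; the
free quantity is the independent mobility noise. The generator computes
all variance components analytically from the configured profiles
(structural dip variance and covariance, latent contributions,
negative-binomial noise at the configured means, and the sampling error of
the per-weekday median baseline) and solves for the category noise SD that
makes the implied correlation equal `target_corr`. Across 100 seeds at the
defaults, the realised single-city r at $n \approx 360$ averages about
0.70 with spread consistent with sampling theory; a `target_corr` at or
near zero is served by clamping the solve at 0.02, which inflates the
mobility noise until the realised correlation is statistically
indistinguishable from zero at this sample size.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: long-term trends and holiday effects in
admissions, weather-driven mobility variation, the gradual (rather than
rectangular) entry into and exit from lockdowns, reporting artefacts of
the real feeds beyond simple missing days, and any epidemic dynamics. The
generator validates the *pipeline*, not the epidemiology.

## Numerical choices and degenerate inputs

* Dates are ISO-8601 everywhere; region/city matching is exact after
  whitespace trimming (case-sensitive).
* Weekday labels are locale-independent (Monday-first index).
* Medians of even-sized samples use the mean of the two central order
  statistics (the R default).
* Zero or missing baselines (weekday median, single-day count) are errors,
  never silent division.
* Correlations need at least 3 complete pairs; intervals need 4 and
  |r| < 1; zero variance in either variable is an explicit error.
* Reporting rounds r and interval bounds to 2 decimals and percent
  differences half away from zero; regression coefficients are reported to
  full precision and rounded only in rendered tables.
* Derived RNG streams use small fixed offsets of the user seed (seed + 1
  for counts, seed + 2 for mobility) so the two generators can be run
  independently yet stay mutually consistent.

## Problem sizes used by the test suite

The suite validates the inference oracle on 100 random samples of n <= 20;
correlation recovery on 100 seeds of a single-city configuration
(n ≈ 360 daily pairs each); lockdown-drop recovery on 60 seeds of the full
three-city configuration (Monte-Carlo mean across seeds within +/-2
percentage points of the injected drops); and end-to-end determinism on
repeated full-pipeline runs. These sizes give sampling error comfortably
below the asserted tolerances while the whole suite stays fast.

## Known limitations

* The regression is a plain OLS on daily pairs; residuals of such series
  are heteroscedastic and autocorrelated, so the p-values are
  anti-conservative for real data. Lag structure and autocorrelation
  correction are out of scope.
* The pipeline treats mobility region labels as opaque strings that must
  match the count cities exactly; no geocoding or fuzzy matching.
* Model-based imputation (Kalman, ARIMA) is out of scope; the seasonal
  split with linear interpolation is the only method offered.

## A minimal run

```{r, eval = FALSE}
library(mobadmit)
bundle <- run_pipeline(pipeline_config(synthetic = synthetic_config(seed = 1)))
bundle$tables$correlation_formatted
bundle$tables$lockdown
```
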