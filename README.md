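# mobadmit

Relating smartphone-derived community mobility reports to daily trauma
outpatient admissions.

During the COVID-19 lockdowns, population movement and trauma admissions
fell together. `mobadmit` is an R package for quantifying that
relationship from two widely archived mobility formats — Google-style
community mobility reports (long format, percent change from a per-weekday
baseline) and Apple-style mobility trends (wide format, volumes indexed to
100 on a baseline day) — together with daily outpatient counts per city
and sex. It is aimed at clinical epidemiologists and hospital planners who
want a reproducible answer to two questions: how tightly did admissions
track mobility, and how much did each lockdown suppress them?

## The method in brief

* **Leisure mobility index.** Per day, the composite
  `MI_L = ¼ [CFB(rr) + CFB(pa) + CFB(ts) − CFB(res)]` over the
  retail/recreation, parks, transit and residential categories;
  residential enters negatively (time at home = compliance), while
  grocery/pharmacy (essential) and workplaces (remote-work artefact) are
  excluded.
* **Outpatient index (AOI).** Daily counts expressed as percent change
  against a baseline matching each provider's convention: per-weekday
  medians of a pre-pandemic reference window (Google convention) or the
  count on a single reference day, 13 Jan 2020 (Apple convention).
* **Gap handling.** Sporadic missing days are filled by seasonal-split
  interpolation: linear interpolation *within each weekday subseries*,
  preserving the weekly cycle.
* **Inference.** Pearson correlation with Fisher-z 95% intervals and
  simple OLS (`AOI = a + b·MI_L`) with F-test, r² and adjusted r², per
  city and pooled across cities, on daily pairs.
* **Lockdown tables.** Average outpatients per day (AO/d) per lockdown vs
  the matched previous-year interval (leap days excluded), with percent
  differences rounded half away from zero.
* **Synthetic data.** A fully seeded generator emulating the study
  conditions (three cities, three fading lockdowns, overdispersed counts,
  weekday seasonality, missing days, tunable mobility–admissions
  correlation), so the complete pipeline runs and is tested without access
  to hospital records.

See `vignettes/mobility-admissions-methods.Rmd` for the full account of
the model, conventions and design choices.

## Worked example

```r
library(mobadmit)
bundle <- run_pipeline(pipeline_config(synthetic = synthetic_config(seed = 1)))
bundle$tables$correlation_formatted
#>   provider     region    r      ci_95 p_value
#> 1   Google       Graz 0.67 0.61; 0.73  <0.001
#> 2   Google  Innsbruck 0.68 0.62; 0.74  <0.001
#> 3   Google     Vienna 0.71 0.66; 0.76  <0.001
#> 4   Google All cities 0.69 0.66; 0.72  <0.001
#> 5    Apple       Graz 0.73 0.68; 0.77  <0.001
#> 6    Apple  Innsbruck 0.76 0.72; 0.80  <0.001
#> 7    Apple     Vienna 0.76 0.72; 0.80  <0.001
#> 8    Apple All cities 0.58 0.55; 0.62  <0.001
```

Each row is the Pearson correlation between the leisure mobility index and
the outpatient index for one city (or all cities pooled) under one
provider's baseline convention, with its Fisher-z 95% interval: mobility
explains roughly half the day-to-day variance in admissions under these
synthetic conditions (generated with `target_corr = 0.7`). Note the pooled
Apple row: single-day baselines give each city a different offset, which
attenuates the pooled correlation relative to the per-city ones.

```r
subset(bundle$tables$lockdown, sex == "total")
#>        city period   sex ao_d_ref  ao_d_cur diff_pct
#>        Graz  first total 149.0109  56.19565      -62
#>        Graz second total 155.1000  91.75000      -41
#>        Graz  third total 149.8182 113.94318      -24
#>   Innsbruck  first total 117.3152  43.95652      -63
#>   Innsbruck second total 107.9750  70.82500      -34
#>   Innsbruck  third total 112.1136  81.52273      -27
#>      Vienna  first total 174.9130  66.73913      -62
#>      Vienna second total 172.3000 103.25000      -40
#>      Vienna  third total 174.5000 124.09091      -29
```

AO/d is the average number of outpatients per day in each lockdown window
and in the same calendar window one year earlier; `diff_pct` is their
rounded percent difference. The generator injected admission drops of
62%, 40% and 27% for the three lockdowns, and the table recovers them —
including the fading of the suppression across successive lockdowns
(compliance decay).

Command-line use (`inst/cli/mobadmit.R`) wraps the same functions:

```sh
Rscript inst/cli/mobadmit.R simulate --seed 1 --out data/
Rscript inst/cli/mobadmit.R run --seed 1 --out results/
```

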