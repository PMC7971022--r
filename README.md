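# wearhome

Compliance with tiered public-health restrictions, measured from the
wearables people already carry. `wearhome` converts 5-minute smartwatch
records — GPS fixes, step counts, heart rate — into two daily mobility
outcomes and quantifies how they shift across COVID-19 intervention
levels:

* **fraction of time spent at home**: the share of a day's 288
  five-minute intervals whose GPS fix falls within a 100 m geofence
  around the residence, divided by 24 h (missing-GPS intervals inherit
  the label of the most recent valid fix);
* **total steps per day** over the same 24 h.

Days without any heart-rate sample (watch not worn) and desert-dust-storm
advisory days are excluded. Each retained participant-day is annotated
with its country's intervention level (tiers 0–3, built-in 2020 calendars
for Cyprus and Greece, overridable via YAML), weekend flag, study year,
weather and a harmonic seasonal pair. The statistics mirror a two-track
design:

* *unadjusted*: per-level means with 95% CIs, one-way ANOVA and
  Bonferroni-capped pairwise comparisons (`level_means()`);
* *adjusted*: a linear mixed model per site and outcome,

  y<sub>ij</sub> = β₀ + **β**<sub>L</sub>·level + β<sub>w</sub>·weekend +
  **β**<sub>wL</sub>·(weekend×level) + β<sub>g</sub>·male +
  β<sub>a</sub>·age + β<sub>y</sub>·year2020 + β<sub>T</sub>·temp +
  β<sub>H</sub>·humidity + β<sub>s</sub>·sin t + β<sub>c</sub>·cos t +
  b<sub>i</sub> + ε<sub>ij</sub>,

  with a participant random intercept b<sub>i</sub>, fitted by REML
  (`fit_mobility_model()`, returning a `mobility_fit` object with the
  usual `print`/`summary`/`coef`/`confint`/`predict`/`residuals`
  methods), plus Wald level contrasts (`level_contrasts()`).

A synthetic-cohort generator (`simulate_cohort()`) with emitted ground
truth makes the whole pipeline testable without any participant data:
it reproduces the study's structure (two cohorts of 53 and 55 children,
Feb 3–Apr 26 windows for 2019 and 2020, level shifts at the study's
effect magnitudes, weekend effects that reverse under lockdown, indoor-
dominated GPS dropout, non-wear days, dust-storm days).

Audience: biostatisticians and digital-epidemiology groups analysing
wearable GPS/actigraphy panels against policy calendars.

## Worked example

```r
library(wearhome)

cfg <- synthetic_config(seed = 42)
cfg$sites$Greece <- NULL
cfg$sites$Cyprus$n_participants <- 10
cfg$study_windows <- data.frame(year = 2020, start = "2020-02-24",
                                end = "2020-04-05")
cfg$sites$Cyprus$dds_days <- c("2020" = 2)

co       <- simulate_cohort(cfg)                 # interval records + truth
daily    <- process_intervals(co$intervals, co$participants)
retained <- apply_exclusions(daily, co$dds_days, co$participants)
tab      <- annotate_days(retained, co$participants, co$weather)

level_means(tab, "fraction_home", site = "Cyprus")
#>   level   n  mean ci95_low ci95_high p_vs_baseline p_vs_previous
#> 1     0 161 0.452    0.438     0.467            NA            NA
#> 2     1 110 0.819    0.801     0.836     1.60e-105     1.60e-105
#> 3     2  56 0.885    0.860     0.909      1.58e-98      1.53e-04
#> 4     3  44 0.855    0.827     0.883      5.03e-81      6.93e-01

fit <- fit_mobility_model(tab, "fraction_home", site = "Cyprus")
fit
#> Mobility mixed model (REML), outcome: fraction_home, site: Cyprus
#>   371 observations, 10 participants (0 rows dropped for missing covariates)
#>                term   estimate        se    ci_low   ci_high          p
#>         (Intercept)  0.3394000 0.1262000  0.092160  0.586700  7.135e-03
#>              level1  0.4154000 0.0205400  0.375100  0.455600  5.822e-91
#>              level2  0.4811000 0.0136800  0.454300  0.507900 9.191e-271
#>              level3  0.4595000 0.0197800  0.420700  0.498200 2.143e-119
#>         weekendTRUE  0.1214000 0.0149800  0.092030  0.150700  5.335e-16
#>  level1:weekendTRUE -0.2107000 0.0204000 -0.250700 -0.170700  5.215e-25
#>  ...
#>   Random intercept var: 0.003694  Residual var: 0.004509

level_contrasts(fit)
#>            comparison estimate     se         p     p_adj adjustment
#> 1 level 1 vs baseline   0.4154 0.0205  5.82e-91  2.91e-90 bonferroni
#> 2 level 2 vs baseline   0.4811 0.0137 9.19e-271 4.60e-270 bonferroni
#> 3 level 3 vs baseline   0.4595 0.0198 2.14e-119 1.07e-118 bonferroni
#> 4  level 2 vs level 1   0.0657 0.0249  8.46e-03  4.23e-02 bonferroni
#> 5  level 3 vs level 2  -0.0216 0.0204  2.88e-01  1.00e+00 bonferroni
```

Reading it: time at home jumps from 45% at baseline to 82–89% across the
lockdown tiers (the generator was configured with weekday shifts of
+0.414/+0.487/+0.452, all recovered within their CIs); weekends add
~12 points at baseline but the weekend×level interactions are negative —
once everyone is home on weekdays, the weekend bump disappears. The
level-3-vs-2 contrast is indistinguishable from zero after capped
Bonferroni adjustment.

One call runs everything and writes every table plus an audit manifest:

```r
run_pipeline(load_pipeline_config(
  system.file("extdata", "demo_pipeline.yaml", package = "wearhome")),
  out_dir = "demo_out", seed = 12)
```

A thin CLI wrapping the same functions lives at
`inst/cli/wearhome.R` (subcommands `simulate`, `process`, `annotate`,
`infer`, `run`).

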