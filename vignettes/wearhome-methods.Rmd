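---
title: "Methods: from 5-minute wearable records to intervention-level effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from 5-minute wearable records to intervention-level effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During the first COVID-19 wave, Cyprus and Greece escalated public health
restrictions through three tiers between March and April 2020. wearhome
quantifies how well a cohort of school-age children complied, using the
smartwatches they already wore for an environmental-health panel study:
GPS fixes, step counts and heart rate recorded every 5 minutes. Two daily
outcomes summarise behaviour:

* **fraction of time spent at home** — the share of a day's 288
  five-minute intervals whose GPS fix lies within a 100 m geofence around
  the participant's residence, divided by the full 24 h;
* **total steps per day** — the sum of interval step counts over the same
  24 h.

## Sensor processing

**Geofence.** A fix is "at home" when its great-circle distance to the
residence is at most 100 m — the radius absorbs consumer-GPS positional
error. The boundary is inclusive (exactly 100.0 m counts as home): the
rule must be deterministic, and ties are broken toward home. Distances
are haversine on a 6,371,000 m sphere; at the 100 m–2 km scales involved,
ellipsoidal corrections are far below GPS noise.

**Missing fixes.** Indoor environments block or reflect GPS, so signal
loss is informative and cannot be dropped. Each missing interval inherits
the label of the most recent valid fix (carry-forward), crossing midnight
within a participant's contiguous record because the rule names only the
most recent valid recording, with no day limit. A leading gap with no
prior fix takes the label of the *next* valid fix — a backward fill that
is this package's own addition, flagged in the processing log. A
participant record with no valid fix anywhere is unresolvable: its days
keep `NA` fractions and are excluded. We impose no cap on the length of
an imputed run; the longest run is logged so analysts can audit extreme
cases.

**Wear days and exclusions.** A day without a single heart-rate sample
means the watch was not worn: the day is excluded. Desert-dust-storm
(DDS) days are excluded too, because the parent study issues stay-indoors
advice on them that would distort the mobility signal. Every excluded
participant-day lands in exactly one audit tally (non-wear, DDS,
unresolvable).

**Aggregation.** `fraction_home` divides at-home time by a fixed 1,440
minutes even when step or heart-rate streams are partially missing — the
outcome is defined against the full day, not against observed time.
Steps sum whatever intervals report, with no rescaling for missing
intervals. Timestamps are local clock time floored to the 0-based 5-min
grid; duplicate (participant, timestamp) rows keep the first occurrence
with a warning, because silent averaging of cloud-sync duplicates would
not be auditable.

## Study design covariates

Intervention levels 0–3 attach per site and date from built-in calendars
(Cyprus: level 1 from Mar 13, 2020, level 2 from Mar 25, level 3 from
Apr 1; Greece: level 1 from Mar 11, level 2 from Mar 16, level 3 from
Mar 23; both windows run Feb 3 – Apr 26). Any date outside the calendar
— in particular the whole 2019 comparison window — is level 0. Calendars
are overridable from YAML so other jurisdictions can reuse the pipeline.

Weekend is Saturday/Sunday of the local calendar. Weather joins on
(site, date) with linear interpolation across gaps of at most 2 days;
longer gaps drop the day with a warning rather than fabricate a
covariate. One sine/cosine pair with period *P* absorbs slow periodic
variation; the default *P* = 30.44 days reads "monthly variability"
literally (the mean calendar month), and *P* is a logged configuration
value so an annual harmonic is one flag away. Month fixed effects would
be the other defensible reading; the harmonic pair was chosen because it
is smooth, uses two degrees of freedom, and nests cleanly in the model.

## The adjusted model

`fit_mobility_model()` fits, per site and outcome,

\[
y_{ij} = \beta_0 + \boldsymbol{\beta}_L \mathrm{level}_{ij}
 + \beta_w \mathrm{weekend}_{ij}
 + \boldsymbol{\beta}_{wL}\,(\mathrm{weekend}\times\mathrm{level})_{ij}
 + \beta_g \mathrm{male}_i + \beta_a \mathrm{age}_i
 + \beta_y \mathrm{year2020}_{ij}
 + \beta_T T_{ij} + \beta_H H_{ij}
 + \beta_s \sin t_{ij} + \beta_c \cos t_{ij}
 + b_i + \varepsilon_{ij},
\]

with level categorical (baseline 0 the reference), a random intercept
\(b_i \sim N(0, \sigma_b^2)\) per participant capturing within-person
correlation of daily outcomes, and \(\varepsilon_{ij} \sim N(0,
\sigma^2)\). Estimation is REML via `lme4`; REML is the conventional
default for variance components and is recorded in the fit object.
Inference is by Wald statistics with normal critical values, which
matches symmetric 95% CIs and is well calibrated here: the study designs
have thousands of participant-days and ~50 participants, and the
package's own null simulations put empirical coverage of every fixed
term within the 90–98% band. Factors that do not vary in a given subset
(e.g. year in a single-season analysis) are dropped from the design
rather than passed to the optimizer as constants; a rank-deficient
design is an error naming the collinear terms, and non-convergence is
surfaced as a flag, never a silent result.

Level contrasts (each level vs baseline and vs the previous level) are
linear functions of the level coefficients with Wald standard errors
from the fitted covariance, Bonferroni-multiplied over the contrast
family and capped at 1 — capping is what produces the characteristic
p = 0.999 entries in per-level comparison tables.

The unadjusted companion, `level_means()`, pools participant-days within
each level (normal-theory CIs, one-way ANOVA, pooled-SD pairwise t tests
with capped Bonferroni). Pooling daily observations ignores clustering
by design: it is the "observed" analysis, and its n per level is
reported so readers can judge it. Severity-stratified summaries reuse
the same code path with a stratum argument.

With the random-intercept variance at zero the mixed model collapses to
ordinary least squares; `random_intercept = FALSE` exposes that limit
explicitly, and the test suite verifies the collapse against a
normal-equations oracle to four decimals.

## The synthetic cohort

The generator is first-class, tested code: it defines the conditions
under which the pipeline's statistical guarantees are demonstrated.
Defaults mirror the study design — Cyprus n = 53 and Greece (Crete)
n = 55 children aged 6–11, observed Feb 3 – Apr 26 of 2019 and 2020,
with per-level weekday shifts in at-home fraction of +0.414/+0.487/+0.452
(Cyprus) and +0.143/+0.231/+0.320 (Greece) over baselines 0.438/0.524,
step shifts of −2531/−3638/−3644 and −1191/−2337/−1961 steps/day over
baselines 8996/8527, a weekend effect (+0.109 at-home, −1002 steps) that
reverses under lockdown (−0.18, +1400), an age gradient of +0.014/year on
time at home, +1024 steps for boys, −29 steps per %RH, and DDS days
(Cyprus 5 in 2020, 4 in 2019; Crete 1 and 2). Where the design needed
values the study conditions do not pin down, they were chosen once at
field-realistic scales and kept: between-participant SDs of 0.05
(fraction) and 1,000 steps, day-to-day SDs of 0.07 and 2,500, indoor GPS
dropout 0.35 vs outdoor 0.15, non-wear probability 0.08 per
participant-day.

Within a day, occupancy is a two-state home/away schedule of contiguous
bouts (1–3 away bouts) whose home dwell equals the day's drawn fraction
rounded to the 5-min grid; the emitted truth stores this realised
occupancy, so with dropout and non-wear switched off the pipeline
recovers it *exactly* — the end-to-end identity the suite asserts.
Out-of-home fixes fall 150–2000 m from home (safely outside the
geofence but local in scale); at-home fixes fall within 80 m (radius
minus a margin). Steps split multinomially over intervals with
near-zero weight at home during 00:00–06:00, so interval totals conserve
the daily draw. Weather is an AR(1) series per site. 2019 reuses level-0
behaviour throughout, reproducing a flat pre-pandemic series.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: GPS position error near the geofence
boundary (fixes are placed strictly inside or outside), multi-day
synchronization outages, within-day autocorrelation of dropout, any
physiological structure in heart rate (presence/absence only), school
holidays other than weekends, and a year-2020 main effect independent of
the interventions. Daily fractions are clamped to [0, 1], which
introduces a small attenuation (< 0.015) at occupancy means above 0.9;
the recovery simulations absorb it comfortably inside their ±0.03 band.

## Simulation studies and numerical choices

The suite's simulation studies use the full Cyprus design (53
participants, both study years, daily-truth fast path): 100 replicates
for null coverage of every fixed term and 50 replicates for recovery of
the configured level effects (±0.03 fraction, ±400 steps). Replicate
seeds follow a fixed package convention — integer offsets from 20200203,
the study window's start date written as a number. Determinism is
absolute: one seed fixes every byte of generator output.

Other conventions: geofence boundary inclusive; carry-forward crosses
midnight, backward fill covers leading gaps; weather interpolation limit
2 days; contrast adjustment Bonferroni with capping; rows with any
missing covariate are dropped list-wise and counted in the fit object.

## Limitations

Home/away is a two-state classification — no stay-point clustering or
multi-microenvironment inference, no accuracy weighting of fixes, and no
causal or interrupted-time-series machinery: the model estimates
adjusted associations between calendar-defined intervention tiers and
behaviour in cohorts that were already instrumented. Table-style CIs for
the observed means pool participant-days; an analysis over participant
means would be wider and is not what `level_means()` computes.
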