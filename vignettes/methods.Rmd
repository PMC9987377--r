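---
title: "Models and design of the alswear pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the alswear pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind the
package: what the synthetic cohort emulates, how each daily physical
activity measure is defined, how the mixed models are specified and
summarized, and where the design was genuinely open and a decision had to
be made.

## The study the package models

A remote digital-phenotyping ALS study: ambulatory adults wear an activity
monitor continuously for about six months and complete smartphone surveys.
Two device types are modelled. The *activity-count* (actigraph-style,
wrist-worn) device reports minute-level activity counts (AC) — a unitless
magnitude summary of the acceleration signal — plus wear-status and missing
flags. The *step-count* (modus-style, ankle-worn) device reports
minute-level step sums and carries no epoch-level wear indicator. Surveys
are the self-entry ALSFRS-RSE and ROADS every 2–4 weeks, with the
staff-administered ALSFRS-R at months 0, 3, and 6. ROADS is simulated
directly on its normed total-score scale; item-level raw-to-normed
conversion is out of scope.

## The synthetic cohort generator

The generator's defaults are the study conditions all experiments use:
40 participants, 180 days, a 50/50 device split, surveys at uniform 14–28
day intervals. Population parameters default to the cohort-level estimates
the models are expected to recover: survey baselines/monthly slopes of
31.6/−0.37 (ALSFRS-R), a +2.86-point self-entry offset with slope −0.48
(ALSFRS-RSE), 84.9/−1.26 (ROADS), and a daily total-activity-count
trajectory of 1,362,438 baseline with −58,631 per month.

Structure, per participant *i* with instrument or activity block *k*:

* random intercept and slope (b₀ᵢᵏ, b₁ᵢᵏ), with SDs σ₀ᵏ, σ₁ᵏ;
* a shared latent severity loading (z₀ᵢ, z₁ᵢ) ~ N(0, I). Each block's
  effects load on it with weight w (`latent_coupling`, default 0.6):
  b = σ·(w·z + √(1−w²)·e), so the correlation between any two blocks'
  slopes is w². This is the single knob that couples activity decline to
  survey decline and induces the measure–survey associations;
* the configured intercept–slope correlation applies to the idiosyncratic
  component e (default 0; nothing in the emulated study pins it down);
* the staff and self-entry ALSFRS share one set of random effects — they
  measure the same construct — which is what produces the high
  within-participant staff/self correlation (r ≳ 0.93 on matched pairs).
  The self-entry baseline is *derived* as staff baseline + offset
  (31.6 + 2.86 = 34.46), so the offset and both baselines stay mutually
  consistent by construction.

Random-effect and residual SDs are not reported by cohort-level summaries,
so they were chosen once as realistic values and not revisited: ALSFRS
intercept SD 6 (close to the observed baseline spread while keeping
ceiling censoring at the 48-point maximum negligible), slope SD 0.5/month
(back-calculated from the reported slope CI width at n = 40), residual SD
1.5 points (consistent with matched staff/self correlations above 0.93);
ROADS 15 / 1.4 / 3; TAC intercept SD 400,000, slope SD 25,000/month, daily
residual SD 200,000 (chosen to reproduce the reported R²m ≈ 0.03 and
R²c ≈ 0.8 orders for activity volume while keeping negative-trajectory
truncation negligible).

**Minute level.** A day's latent TAC is the participant's linear trajectory
plus daily Gaussian noise (truncated at 0; at the default parameters
truncation is ~5 SDs away and immaterial). It is spread over the 1440
minutes by a sin² circadian bump across the waking window (06:00–22:00,
2% of mass at night) and multiplied by mean-one gamma noise (shape 1), so
minute values are non-negative and the daily expectation is preserved
exactly — no truncation bias enters the trajectory. At these defaults a
baseline day has ~250 minutes above the 1853-count active threshold,
matching the order observed with wrist devices in ALS. The step device
draws stepping minutes with circadian probability scaled so the expected
daily sum equals the latent step trajectory, and gives stepping minutes a
shifted negative-binomial cadence (mean 9.35, chosen with the dispersion
0.9 so the mean/median/95th-percentile cadences sit near 9/7/26
steps-per-minute).

**Missingness.** Actigraph days get a 4-hour charging gap with probability
0.15 (minutes *missing*), short non-wear blocks (Poisson mean 1/day,
geometric mean length 60 min; device on a table records ~0 AC, *wear*
flag off), and a full-day off probability of 0.10; the step arm has a
0.15 daily off probability and loses night hours automatically (no steps
logged). These rates were set to land near the reported compliance
medians (~21 valid hours on an actigraph valid day, ~12–13 on a step-arm
valid day, ~80–90% of days valid) and are not varied by any test.

**Determinism.** Every participant draws from substreams keyed by
(master seed, participant index) — one stream for profile + surveys, one
for wearable days — so regenerating with more participants never perturbs
existing ones, and identical (config, seed) reproduces the cohort
byte-for-byte.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: within-day bout autocorrelation (minutes are
conditionally independent, so fragmentation levels like ASTP ≈ 0.6 sit
above the ~0.39 seen in real wrist data), cadence decline (volume declines
through fewer stepping minutes, not slower stepping), informative
missingness (gaps are independent of disease state), dropout, device
swaps, and seasonal or day-of-week structure.

## Validity, imputation, daily measures

*Valid hour*: clock-aligned (minutes 60h..60h+59). For the activity-count
device all 60 minutes must be worn and non-missing — "60 consecutive
minutes" is read as a full clock hour, matching the hour-level bookkeeping
used everywhere else; for the step device an hour needs ≥ 1 step. *Valid
day*: ≥ 8 valid hours, not necessarily consecutive. Only valid days are
used downstream.

Imputation (activity-count arm only) fills every minute lacking an
observed worn AC — missing *or* non-wear — with the mean of that
minute-of-day's observed worn values across the participant's valid days.
The donor pool is the participant's valid days: they are the only
wear-qualified day set the pipeline constructs. A minute-of-day with no
donor on any valid day falls back to 0 with a warning, preserving the
1440-analyzable-minutes identity on degenerate inputs. Imputation is
idempotent and never alters an observed worn value. Note the estimand
consequence: an imputed minute carries the participant's across-study mean
at that clock minute, so a declining trajectory is flattened by roughly
the imputed-minute fraction. That is a property of the measure (as
defined), not an estimator defect; the parameter-recovery experiment
therefore disables the missingness model to isolate the estimator, and a
separate test documents the attenuation qualitatively.

Daily measures follow the definitions in the package README. Numerical
conventions held fixed: the active/sedentary threshold is strict
(AC = 1853 is sedentary); transition probabilities condition on minutes
0..1438 and are NA (never 0) when the denominator is empty; transitions do
not wrap across midnight; cadence statistics are computed over minutes
with ≥ 1 step (the percent-time-at-1–15-steps family implies zero-step
minutes are non-activity), with the 95th percentile by linear
interpolation between order statistics (R type 7); the percent-time band
denominator is minutes inside valid hours, because the step device has no
wear flag and an all-1440 denominator would conflate non-wear with
inactivity; maximum consecutive cadences require a full window; the peak
performance index is the mean of the 30 largest minute values.

## Mixed models

All models are linear mixed models with participant-specific random
intercept and slope (unstructured 2×2 covariance), fitted by REML —
variance components feed R², and REML is the conventional default.
Elapsed time is converted to months as days / 30.4375 (mean Gregorian
month). Fixed-effect inference uses Wald 95% intervals and Satterthwaite
denominator degrees of freedom. A singular random-effect covariance
triggers a diagonal refit, flagged; non-convergence is reported
explicitly. Rank-deficient fixed-effect designs are rejected before
fitting.

R²m and R²c follow the Nakagawa–Schielzeth variance decomposition with the
Johnson random-slope extension: the fixed variance is the variance of the
fixed-effect linear predictor over the observed design, and the random
variance is the mean over observations of zᵀGz with z = (1, slope
variable), which accommodates the observation-dependent slope variance.

The relative-change summary evaluates each participant's conditional mean
(fixed + predicted random effects) at t = 0 and exactly t = 6 months, and
counts participants with |relative change| ≥ 10% whose direction matches
the sign of the population slope; zero-baseline participants are excluded
from both numerator and denominator.

Association models regress a survey score on the standardized 15-day
window mean of a daily measure. Two open points were settled as follows
and held fixed: the window includes the survey day itself ([−7, +7]
inclusive; "7 days before and after" is ambiguous on inclusion and the
symmetric reading was chosen), and the random slope is on the *covariate*,
not on time — time is not among these models' fixed effects, and a
covariate slope captures per-participant association heterogeneity.
Standardization is pooled across participants and timepoints (n−1
denominator); no multiple-testing correction is applied, and the composite
"significant for both surveys" flag uses p < 0.05 for each instrument.
Matched staff/self correlations take, per staff administration, the
self-entry score with the smallest |date offset| within ±28 days, ties
broken toward the earlier survey (the tie rule is unstated in the emulated
design; earlier-survey is deterministic and logged), computed on integer
scores without jitter.

The sensitivity analysis masks days cyclically from each participant's own
baseline (weeks are 7-day blocks of participant time, not calendar weeks,
matching the participant-anchored time axis), fits the TAC trajectory on
the retained days for each of the nine schedules, and reports percent
deviations from the all-data fit. Masking is applied after validity
filtering: the experiment emulates *not collecting* data, so the non-wear
structure inside retained weeks is unchanged.

## Problem sizes in the test suite

The suite validates the estimators with simulation sizes chosen to keep a
full run on one CPU comfortable while leaving the Monte-Carlo criteria
self-calibrating (every recovery check compares a mean across replicates
to the truth at 3 Monte-Carlo standard errors, so the criterion scales
with the replicate count): 200 survey-arm cohorts for survey fixed-effect
recovery and slope CI coverage (checked against the [90%, 99%] band);
60 minute-level cohorts for TAC recovery through the full
validity-imputation-derivation pipeline (missingness disabled, as above);
40 cohorts for the monitoring-frequency experiment, with the ≥ 90%
detection threshold applied per scenario; 1000 random grids for the
brute-force oracle equivalence of every daily-measure operation. Moment
checks on the generator itself use 500-participant cohorts.

## Known limitations

The fragmentation measures (ASTP/SATP) are structurally valid but sit at
synthetic levels, because minutes are conditionally independent within a
day; conclusions about fragmentation in real cohorts need real data. The
step arm's cadence distribution is stationary within participants. The
generator produces a single enrolment date per cohort and no dropout. The
association models are contemporaneous only — no lagged or cross-lagged
structure. ActiGraph vendor daily measures (light/moderate/vigorous
minutes, calories, METs, sleep, locomotion) derive from proprietary
algorithms and are intentionally not re-created; the pipeline's
measure-generic model code runs unchanged on such columns if supplied.
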