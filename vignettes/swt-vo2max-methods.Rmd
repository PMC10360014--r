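---
title: "Methods: smartwatch VO2max estimation and AMS risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartwatch VO2max estimation and AMS risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(swtams)
```

## Scope

`swtams` implements a complete, testable pipeline around a common
sports-medicine workflow: estimating maximum oxygen consumption (VO2max)
from a *submaximal* outdoor run recorded by a wrist device (heart rate and
speed at 1 Hz), validating that estimate against a reference measurement
with standard method-agreement statistics, and using the estimate together
with red-cell distribution width (RDW-CV) to predict acute mountain
sickness (AMS) risk. Because raw device traces and clinical datasets of
this kind are rarely shared, the package also ships a synthetic-data
generator with *known* ground truth, so every stage can be verified
end to end.

## The physiological model

During steady aerobic running, oxygen cost is approximately linear in
speed. The package uses the running economy convention

> theoretical VO2 (mL·kg⁻¹·min⁻¹) = 3.5 × speed (km/h),

and the near-linear heart-rate–VO2 relationship between roughly 50% and
100% of maximum heart rate. The estimator therefore: (1) finds stretches of
the run where heart rate and speed are reliably coupled, (2) summarizes
them as (mean HR, theoretical VO2) points, (3) fits a weighted straight
line through those points, and (4) reads the line off at the participant's
maximum heart rate (default `220 − age`), rounding half-up to an integer as
consumer devices do.

## The estimation pipeline, stage by stage

`swt_vo2max()` is the single fitting entry point; it returns a classed
object with `print()`, `summary()`, `coef()`, `predict()`, `plot()` and
`residuals()` methods. Internally:

1. **Filtering** — centred 5 s moving averages of heart rate and speed
   (`moving_average()`). Five seconds suppresses sample noise at 1 Hz
   without smearing the shortest (20 s) usable segments; windows shrink at
   the edges rather than padding.
2. **Activity detection** — a sample is active when both filtered series
   are locally increasing (`detect_activity()`): the signature of coupled
   effort.
3. **Artifact exclusion** (`apply_exclusions()`) — three rules remove
   stretches where speed no longer reflects oxygen demand:
   `downhill_pattern` (filtered HR falls ≥ 5 bpm over 10 s while speed
   stays ≥ 6 km/h), `hr_rise_at_zero_speed` (HR climbs ≥ 5 bpm during a
   standstill of ≥ 10 s), and `short_high_intensity` (a top-zone burst
   shorter than 20 s whose HR rises into its peak faster than 1 bpm/s —
   an anaerobic sprint, not steady aerobic effort). The slope is measured
   from the span start to its HR peak because a spike that rises and falls
   within the span has a near-zero endpoint-to-endpoint slope.
4. **Segmentation** (`segment_by_zone()`) — surviving samples are grouped
   into segments within one HR zone (bands of %HRmax:
   [50,60), [60,70), [70,80), [80,90), [90,100]); a segment must last
   20 s–10 min and drift less than 5 bpm. Samples under 50% HRmax are never
   reliable.
5. **Weighting** (`weight_segments()`) — weight = duration × preferred
   window factor (1 if 30 s–4 min, else 0.5) × zone factor
   (1 + 0.25·(zone − 1): higher zones constrain the extrapolation more),
   normalized to sum to 1.
6. **Fit and extrapolation** (`estimate_vo2max()`) — weighted least squares
   of theoretical VO2 on mean HR, evaluated at HRmax. Quality is `ok` only
   with at least 3 segments and a physiologic value (10–90); fewer segments
   flag `low_segments`; fewer than two distinct HR levels flag
   `no_reliable_data`.

All thresholds live in `swt_config()` and are documented there; the numbers
above are defaults, not magic constants.

## The synthetic generator and its noise model

`simulate_run_session()` produces a 1 Hz trace from a
`participant_profile()` and a scenario of named phases (warm-up, ramps,
steady blocks, stops, downhill and sprint artifacts). During clean phases,

> HR = hr_rest + (hr_max − hr_rest) · (3.5 · speed / true_vo2max),

followed through a first-order lag (τ = 30 s), so the pipeline must cope
with HR trailing speed like a real cardiovascular response. Artifact phases
deliberately violate the coupling in exactly the ways the three exclusion
rules target.

The HR noise is *smooth*: a low-frequency wander built from two
random-phase sinusoids (periods 10 and 15 min) with total standard
deviation `hr_noise_sd` (default 1 bpm), plus optional white jitter
(default 0). This choice is deliberate. Wrist devices report heavily
pre-filtered PPG-derived heart rate, whose residual error drifts slowly;
white per-sample noise of comparable amplitude would be both unrealistic
and structurally destructive — activity detection requires runs of
consecutive positive filtered differences, which i.i.d. noise destroys with
high probability. The white-jitter knob exists to demonstrate precisely
that degradation.

`simulate_cohort()` generates the clinical layer: reference VO2max
~ round(Normal(30.17, 5.01)); AMS drawn from a logistic model with
generative odds ratios 0.770 per VO2max unit and 1.263 per RDW-CV unit;
device VO2max = reference + 1.11 + Normal(0, 1.73), rounded (a constant
error of about +1 with limits of agreement ±3.4); Lake Louise symptom items
sampled consistently with the AMS label (`ams_from_lls()`: headache ≥ 1 and
total ≥ 3); plus demographic and haematology columns with realistic
margins. Every parameter is a `cohort_config()` argument.

## Agreement and risk statistics

`vo2_agreement()` bundles the standard method-comparison panel: constant
error (mean ± SD of device − reference), the paired t test, Pearson r/r²,
two-way intraclass correlations (consistency `ICC(C,1)` and absolute
agreement `ICC(A,1)` from the two-way ANOVA mean squares), MAE/MAPE, and
Bland-Altman bias with 1.96·SD limits of agreement.

The risk layer provides Woolf (log-OR) confidence intervals for 2×2 tables
(`odds_ratio_2x2()`, Haldane–Anscombe 0.5 correction on zero cells),
logistic models via `fit_logistic()` (a thin, validating wrapper over
`stats::glm` that detects complete separation and suppresses meaningless
Wald intervals), ROC curves with the Mann-Whitney AUC (ties count ½),
DeLong standard errors and paired AUC comparisons
(`compare_auc_paired()`), and Youden-optimal operating points
(`youden_optimal()`, ties broken toward specificity). The DeLong placement
values use the O(n log n) midrank formulation, so cohorts of tens of
thousands are cheap; correctness is pinned by brute-force O(n²) oracles and
by `pROC` in the test suite.

## Numerical and statistical choices worth knowing

- **z = 1.96** is used for all normal-theory intervals (Woolf, Wald,
  limits of agreement), matching the reporting convention of the clinical
  literature rather than `qnorm(0.975)`; third-decimal differences versus
  other software stem from this and from their internal rounding.
- **Rounding is half-up** (`round_half_up()`), as devices report, not
  banker's rounding.
- **Recovery testing counts per coefficient.** A 2·SE band has nominal
  coverage 95.45%, so recovery of the generative odds ratios is asserted
  on checks pooled over both coefficients across seeds; a per-seed joint
  criterion would have nominal rate ≈ 92.6% and would fail a perfectly
  calibrated estimator.
- **Refits use the generative predictor.** Refitting the outcome model on
  the noisy device VO2max measures classical measurement-error attenuation
  (λ ≈ 0.89 at the default error SD), not calibration; the package's
  recovery checks therefore refit on the reference value and the
  attenuation itself is observable by swapping predictors.
- **Problem sizes are package choices**: the demonstration cohort of 46 and
  session lengths of ~25 min mirror a realistic field study; property
  checks run at n = 2000 where asymptotics are trustworthy yet a full suite
  stays under a few minutes on one CPU.

## Worked example

```{r example, eval = FALSE}
p <- participant_profile(id = 1, age = 32, sex = "female", height = 166,
                         weight = 58, hr_rest = 61, true_vo2max = 38)
ses <- simulate_run_session(p, scenario_clean_ramp(), seed = 42)
fit <- swt_vo2max(ses)
summary(fit)

coh <- simulate_cohort(cohort_config(n_participants = 46, seed = 42))
vo2_agreement(coh$vo2max_swt, coh$vo2max_cpet)
fit_logistic(ams ~ vo2max_swt + rdw_cv, coh)
```

A fully scripted run — cohort CSV, agreement and risk JSON reports, a
config YAML with an md5-stamped log — is available as
`run_full_pipeline(pipeline_config(seed = 1), "out/")`, and a command-line
interface with the same operations ships in `inst/cli/swtams.R`.

## Limitations

The generator is a tool for verifying the pipeline, not a physiological
simulator: it has no thermoregulatory drift, no cardiac drift within
steady phases beyond the configured wander, and independent VO2max and
RDW-CV (any real correlation with age, sex or haematology is not modelled
beyond what the generative logit implies). The downhill rule can only see
HR/speed discordance — actual stride or grade information is not available
from heart rate and speed alone. Extrapolation to `220 − age` inherits that
formula's well-known individual error; `participant_profile()` accepts a
measured HRmax where one exists.
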