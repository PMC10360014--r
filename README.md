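# swtams

Smartwatch-based VO2max estimation and acute mountain sickness (AMS) risk
modelling, with a synthetic-data generator so the whole pipeline is
verifiable against known ground truth.

## The science in one paragraph

Maximum oxygen consumption (VO2max) is the standard measure of aerobic
fitness; the gold-standard measurement (cardiopulmonary exercise testing,
CPET) requires exhausting, lab-based exercise. Wrist devices instead
estimate VO2max from a *submaximal* outdoor run: during steady aerobic
effort, oxygen cost is roughly linear in running speed
(`theoretical VO2 = 3.5 × speed in km/h`) and heart rate is roughly linear
in oxygen uptake, so a line fitted through (heart rate, theoretical VO2)
points from reliable stretches of the run can be extrapolated to maximum
heart rate. Lower fitness — together with higher red-cell distribution
width (RDW-CV) — also predicts acute mountain sickness after rapid ascent,
which makes an accurate wrist-device VO2max clinically useful for
pre-travel risk screening. This package implements the full chain:
signal filtering, activity detection, artifact exclusion, heart-rate-zone
segmentation, weighted extrapolation, method-agreement statistics against a
reference, and the AMS risk layer (odds ratios, logistic models, ROC/AUC,
Youden cutoffs, paired DeLong comparison).

## Worked example

```r
library(swtams)

# a participant with known true VO2max, and a clean simulated run
p <- participant_profile(id = 1, age = 32, sex = "female", height = 166,
                         weight = 58, hr_rest = 61, true_vo2max = 38)
ses <- simulate_run_session(p, scenario_clean_ramp(), seed = 42)
fit <- swt_vo2max(ses)
summary(fit)
```

```
Smartwatch VO2max estimate: 38 mL/kg/min (quality: ok)
  13 segments; VO2 = -18.191 + 0.3012 x HR, read at HRmax = 188 bpm

Reliable segments:
 start  end duration zone mean_hr mean_speed theoretical_vo2  weight
    88  168       81    2   118.5      4.945           17.31 0.05402
   169  279      111    2   123.3      5.329           18.65 0.07403
   280  432      153    2   128.3      5.749           20.12 0.10204
   433  458       26    2   131.2      6.216           21.76 0.00867
   459  581      123    3   134.0      6.486           22.70 0.09844
   582  680       99    3   139.1      6.820           23.87 0.07923
   681  776       96    3   144.2      7.262           25.42 0.07683
   777  854       78    3   148.6      7.591           26.57 0.06242
   855  971      117    4   153.0      8.002           28.01 0.10924
   972 1084      113    4   157.9      8.362           29.27 0.10551
  1085 1182       98    4   162.9      8.847           30.96 0.09150
  1183 1251       69    4   167.3      9.232           32.31 0.06443
  1252 1320       69    5   170.9      9.388           32.86 0.07363
```

The estimate recovers the generative truth (38) exactly here; across random
profiles the pipeline's mean absolute error is well under 1 mL·kg⁻¹·min⁻¹
on clean runs. `fit` is an ordinary model object: `coef(fit)`,
`predict(fit, hr = 170)`, `plot(fit)` and `residuals(fit)` behave as you'd
expect.

The clinical layer works the same way on a simulated cohort:

```r
coh <- simulate_cohort(cohort_config(n_participants = 46, seed = 42))
vo2_agreement(coh$vo2max_swt, coh$vo2max_cpet)
```

```
Method agreement on 46 pairs (estimate vs reference):
  constant error: 1.13 (SD 1.95); t(45) = 3.93, p = 0.000289
  Pearson r = 0.907 (r^2 = 0.822); ICC consistency 0.902, absolute 0.875
  MAE = 1.913, MAPE = 6.70%
  Bland-Altman: bias 1.13, 95% LoA [-2.69, 4.95] (width 7.65)
```

```r
fit_logistic(ams ~ vo2max_swt + rdw_cv, coh)
```

```
Logistic risk model (n = 46, logLik = -30.95)
        term     coef      se     or    ci_low ci_high      p
 (Intercept) -2.19700 3.11000 0.1111 0.0002504  49.300 0.4798
  vo2max_swt -0.04358 0.06975 0.9574 0.8350000   1.098 0.5321
      rdw_cv  0.27290 0.22220 1.3140 0.8499000   2.031 0.2194
```

At n = 46 the confidence intervals are wide, as in any real field study of
that size; at n = 2000 the same generator yields AUCs around 0.76 (device
VO2max alone) and 0.78 (combined with RDW-CV), and the refitted odds ratios
recover the generative values (0.770 and 1.263) within 2 standard errors in
about 96% of seeds.

An end-to-end scripted run — cohort CSV, agreement/risk JSON reports,
config YAML, md5-stamped log — is one call:

```r
run_full_pipeline(pipeline_config(seed = 1), "out/")
```

and the same operations are available from the shell via the bundled CLI,
e.g. `Rscript $(Rscript -e 'cat(system.file("cli/swtams.R", package="swtams"))') simulate-cohort --n 46 --seed 1 --out cohort.csv`.

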