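# matchcharts

Personalized reference charts for functional recovery after total knee
arthroplasty (TKA), built from the observed trajectories of *matched*
previous patients rather than from the whole population.

Recovery of the Timed Up and Go test (TUG; seconds to rise from a chair,
walk 3 m, return and sit — lower is better, positively skewed) is highly
variable across patients, so a single population percentile band is too
wide to guide an individual's care. `matchcharts` instead estimates an
index patient's prognosis from the recovery data of the *m* previous
patients most similar to them at baseline:

1. **90-day anchor imputation.** Assessments arrive at irregular days, so
   a broken-line linear mixed model with knots at postoperative days
   0/14/50/90 (boundary 180) is fit by REML:
   *y*<sub>ij</sub> = Σ<sub>k</sub> (β<sub>k</sub> + b<sub>ik</sub>) B<sub>k</sub>(t<sub>ij</sub>) + ε<sub>ij</sub>,
   with b<sub>i</sub> ~ N(0, Ω). Each patient's BLUP at day 90 is the
   matching anchor.
2. **Predictive mean matching.** OLS of the anchor on age, sex, BMI and
   preoperative TUG defines a linear predictor; the donors are the *m*
   pool patients whose predicted anchor is nearest the index patient's —
   so each baseline characteristic is weighted by its relation to the
   outcome, and new patients need no postoperative data to be matched.
3. **Location–scale–shape donor fit.** The donors' pooled observations
   are fit with a Box–Cox Cole–Green (LMS) model — median μ(t) (cubic
   spline, 3 df), scale σ(t) and skewness ν(t) (1 df each) as smooth
   functions of time — yielding percentile curves, 50% prediction
   intervals and z-scores.
4. **Tuning and calibration.** *m* is chosen by leave-one-out
   within-sample testing: mean z-score bias, 50%-interval coverage
   (nominal 0.50) and interval width per *m*; decile calibration tables
   compare predicted and observed medians.

A synthetic TKA cohort generator (`generate_cohort()`) with realistic
covariate marginals, covariate-dependent exponential recovery curves and
exposed ground truth makes the whole pipeline testable end to end.

## Worked example

```r
library(matchcharts)

sim   <- generate_cohort(cohort_config(n_patients = 200, seed = 42))
train <- validate_cohort(sim$cohort)$cohort

bs <- fit_brokenstick(train)
bs
#> <brokenstick_fit>
#>   fixed effects (s at knots):
#>     k0    k14    k50    k90   k180
#> 23.868 14.866 10.296  8.814  8.839
#>   sigma^2 = 2.0381; random effects: unstructured; 200 anchors

mm <- fit_matching_model(bs$anchors, train$covariates)
mm
#> <matching_model> anchor ~ age + sex + bmi + preop
#> (Intercept)         age         sex         bmi       preop
#>      4.5299      0.0270      0.5315      0.0095      0.2045
#> standardized (s):
#>    age    sex    bmi  preop
#> 0.2306 0.2664 0.0547 0.9678
#> R^2 = 0.437, n = 200
```

The fixed effects trace the population recovery shape: ~24 s immediately
after surgery, back below the 10 s mark by day 50. In the matching model
the preoperative time dominates (standardized coefficient 0.97 s — several
times the BMI weight), so matching is preop-led but outcome-weighted.

A band for a new patient — 55-year-old male, BMI 30 kg/m², preoperative
TUG 8 s — from his 35 nearest donors:

```r
pred <- neighbors_prediction(train,
          data.frame(age = 55, sex = "male", bmi = 30, preop = 8),
          m = 35, bs_fit = bs, model = mm)
subset(as.data.frame(pred$band), time %in% c(7, 14, 50, 90, 180))
#>  time   q10   q25   q50   q75  q90
#>     7 10.78 12.30 14.34 16.84 19.6
#>    14  9.97 11.39 13.27 15.55 18.0
#>    50  7.15  8.19  9.51 11.04 12.6
#>    90  6.32  7.25  8.40  9.66 10.9
#>   180  6.52  7.52  8.65  9.77 10.8
```

Read: at day 50 half of comparable patients are expected between 8.2 and
11.0 s (the 50% prediction interval), with median 9.5 s. An observed value
can be placed on the chart as a z-score with `z_score(pred$fit, time, value)`.

Tuning and calibration on a training cohort:

```r
tr  <- tune_m(train, mm, m_grid = c(10, 20, 35, 60, 100, 199))
loo <- loo_predictions(train, mm, tr$optimal_m)
calibration_table(loo$pairs$predicted, loo$pairs$observed)
```

A command-line front end wrapping the same functions (subcommands
`simulate`, `fit`, `match`, `tune`, `predict`, `calibrate`, `run`) is
installed at `system.file("cli", "matchcharts.R", package = "matchcharts")`.

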