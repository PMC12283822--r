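# survarmeta

Arm-level variability meta-regression for time-to-event outcomes:
assessing the potential of precision treatment from published
Kaplan–Meier curves.

## What it does, and for whom

If individuals responded differently to an active drug (verum) than to
placebo, the *dispersion* of the outcome would differ between the two
arms of a randomized trial. For survival outcomes this can be tested
without individual patient data: digitize the published Kaplan–Meier
curves, reconstruct individual time-to-event records from the step
coordinates and the number-at-risk table, fit a censored Weibull model
per arm, and compare the log standard deviation of time to death between
verum and placebo arms across trials. The package is aimed at
biostatisticians and meta-analysts studying treatment-effect
heterogeneity — in particular for glucose-lowering drugs in large
cardiovascular outcome trials (CVOTs), where all-cause mortality is the
one outcome free of competing risks.

The core model is a weighted random-intercept meta-regression with arms
*j* nested in trials *i*:

log SD_ij = β₀ + β₁ trt_ij + β₂ log Mean_ij + b_i + ε_ij,
  b_i ~ N(0, τ²), ε_ij ~ N(0, v_ij),

with trt coded placebo = 0 / verum = 1, v_ij the delta-method variance of
the arm's log SD (observations weighted by 1/v_ij), τ² estimated by
restricted maximum likelihood on a grid-refined profile, fixed effects by
generalized least squares, and Wald 95% intervals. β₁ = 0 means equal
variability in both arms — no footprint of treatment heterogeneity.
Per-predictor models add a clinical covariate and its interaction with
treatment to screen for predictors of heterogeneity.

## Worked example

Simulate a 10-trial portfolio with a known treatment effect on log(SD)
of −0.036 and between-trial heterogeneity τ = 0.05, run the full chain
(render curves → reconstruct records → Weibull per arm →
meta-regression), and inspect the result:

```r
library(survarmeta)

truth <- portfolio_truth(n_trials = 10, beta_treatment = -0.036,
                         tau = 0.05, seed = 1)
run <- run_pipeline(pipeline_config(simulator = truth, seed = 1))

run$cohort$log_sd_summary
#>     group     mean   median      min      max
#> 1 placebo 5.389902 5.275588 5.142953 5.870874
#> 2   verum 5.360583 5.336770 5.062409 5.715188

print(run$primary)
#> Weighted random-intercept meta-regression (primary)
#>   20 arms in 10 trials; tau^2 = 0
#>           estimate     se  ci_low ci_high
#> intercept   0.3786 0.8382 -1.2644  2.0215
#> treatment  -0.0325 0.0597 -0.1494  0.0844
#> log_mean    0.8924 0.1515  0.5954  1.1894
```

For this seed the adjusted verum-minus-placebo difference in log(SD) is
−0.0325, close to the generative effect of −0.036; a single 10-trial
portfolio carries limited information, which is why the validation suite
judges recovery over hundreds of replications. The per-group summary shows the unadjusted arm-level log(SD) values
(around 5.4–5.5 on the months scale, i.e. standard deviations of
200–250 months — far beyond any trial's follow-up, which is why the
Weibull moments are extrapolated rather than restricted). The primary
fit prints the adjusted verum-minus-placebo difference in log(SD)
(`treatment` row) with its Wald interval and the REML estimate of τ²;
a negative value means greater variability of time to death under
placebo. `screen_all_predictors(run$arms, covariates)` tabulates the 12
treatment-interaction models, and `subgroup_fit` restricts the primary
model to one drug class.

Real digitized data enter the same way through CSV files
(`pipeline_config(curves_csv = ..., risk_csv = ..., covariates_csv =
...)`) with the schemas written by the simulator: curve coordinates
(`trial_id,arm,time_months,survival`), number-at-risk tables
(`trial_id,arm,time_months,n_at_risk[,total_events]`) and one covariate
row per trial or arm.

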