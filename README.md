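# raes — risk-adjusted EWMA survival monitoring and predictive biomarker discovery

`raes` asks a question that a single log-rank test cannot answer: *as
patients accrue on a trial arm, is their survival risk running above or
below what a reference model predicts for them — and for which
biomarker-defined subgroups?* It was built for two-arm oncology settings
(the motivating case is advanced pancreatic cancer treated with
gemcitabine-based regimens, where overall survival is short and
treatment benefit may be confined to a biomarker-defined subset), but
applies to any right-censored cohort with baseline covariates and
continuous biomarkers.

## The method

**Phase I.** A Cox proportional hazards model is fit to the control
(reference) arm:

    h(t | x) = h0(t) * exp(beta' x)

with the Breslow estimator of the baseline cumulative hazard
Lambda0(t) (increments d_j / sum_{i in R(t_j)} exp(beta' x_i); Efron or
Breslow handling of ties). The fit is checked with a Schoenfeld-residual
proportional-hazards diagnostic.

**Phase II.** Each test-arm patient i, in monitoring order, gets a
risk-adjusted score built on the martingale residual
M_i = delta_i − Lambda_i, where Lambda_i = Lambda0(t_i) exp(beta' x_i)
is the patient's expected event count under the Phase-I model:

    U_i = (delta_i − Lambda_i) / sqrt(Lambda_i)

(positive = worse survival than predicted, negative = better). The
scores are EWMA-smoothed, Z_t = lambda U_t + (1−lambda) Z_{t−1}, and
compared to time-varying control limits calibrated by Monte Carlo —
in-control sequences are simulated from the fitted Phase-I model itself
— so that the per-case false-alarm rate equals a target alpha (default
0.5%, i.e. one false alarm per 200 monitored cases). A low-side
crossing flags significantly *improved* survival under the test
treatment; a high-side crossing flags deterioration.

**Biomarkers.** For each continuous marker the package finds the
maximally selected log-rank cut-point (the split maximizing the
standardized log-rank statistic), tests the treatment-by-marker-class
interaction in a multivariable Cox model, assesses the stability of the
dichotomized interaction over bootstrap resamples, and reruns the whole
two-phase chart inside each marker class to locate
treatment-sensitive subgroups.

**Synthetic cohorts.** Because trial data of this kind are rarely
public, `sim_config()`/`simulate_cohort()` generate cohorts with the
assumed structure — arm sizes 246/234, realistic covariate mixes,
log-normal biomarkers, a Weibull baseline tuned to a ~5.9-month control
median, configurable prognostic effects and threshold interactions —
with known ground truth for every downstream stage.

## Worked example

```r
library(raes)

cfg <- sim_config(seed = 42,
  interactions = list(list(marker = "HER2", quantile = 0.5, loghr = -0.6)))
cohort <- simulate_cohort(cfg)   # 480 patients, benefit only in high-HER2

ctrl <- cohort[cohort$arm == "control", ]
fit  <- fit_cox(ctrl, c("ecog", "eod", "pi"))
print(summary(fit), digits = 3)
#>   covariate    coef    hr hr_low hr_high        p
#> 1      ecog -0.8157 0.442  0.313   0.625 3.59e-06
#> 2       eod  0.8689 2.384  1.768   3.216 1.27e-08
#> 3        pi  0.0049 1.005  0.998   1.011 1.40e-01

chart_cfg <- chart_config(lambda = 0.1, alpha = 0.005, seed = 43)
limits <- calibrate_limits(fit, ctrl, 234, chart_cfg)
chart  <- monitor_sequence(cohort[cohort$arm == "treatment", ], fit,
                           limits, chart_cfg)
chart
#> Risk-adjusted EWMA chart: 234 monitored case(s)
#>   low-side signals (improved survival): 16, 17, 18, ..., 77, 88
#>   high-side signals (worse survival):   136, 137, 229, 230, 231
plot(chart)
```

The interpretation: runs of low-side signals are stretches of the
monitoring order where test-arm patients outlived the control-arm
model's prediction by more than chance at the 0.5% per-case level.

```r
cp <- max_logrank_cutpoint(cohort, "HER2")
ir <- interaction_cox(cohort, "HER2", cp$cutpoint)
ir
#> Treatment x HER2 interaction at cut-point 5033.57
#>   interaction HR 0.670 (95% CI 0.462-0.971), p = 0.03444
#>   low class (n=211): treatment HR 0.904 (0.680-1.201), p = 0.4864; median OS 5.55 vs 6.28 months
#>   high class (n=269): treatment HR 0.574 (0.445-0.742), p = 2.182e-05; median OS 9.09 vs 6.14 months
```

The interaction HR below 1 with a strong within-class contrast (HR 0.57
in the high class, null in the low class) recovers the planted
treatment-sensitive subgroup; `bootstrap_cutpoint_stability()` and
`subgroup_charts()` then quantify how stable that finding is and where
the chart signals inside each class.

The whole analysis — simulate/read, baseline table, Cox screening,
global chart, cut-points, interactions, bootstrap, subgroup charts —
runs as one call via `run_pipeline(pipeline_config(...))`, or from a
shell via the thin wrapper `inst/scripts/raes-pipeline.R`; every stage
writes a CSV plus a `manifest.json` with the seeds needed to regenerate
it exactly.

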