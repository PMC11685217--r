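---
title: "Risk-adjusted EWMA monitoring of survival outcomes: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-adjusted EWMA monitoring of survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raes)
```

This vignette is the package's own account of its statistical
machinery: the two-phase risk-adjusted chart, the biomarker pipeline
around it, what the synthetic-cohort generator does and does not
emulate, and the numerical and design choices that were genuinely open.

## 1. The two-phase monitoring model

Phase I fits a Cox proportional hazards model
$h(t\mid x) = h_0(t)\,e^{\beta^\top x}$ to the reference (control) arm
by Newton–Raphson maximization of the partial likelihood, with Efron
(default) or Breslow handling of tied event times, step-halving, a
gradient tolerance of $10^{-8}$ and at most 100 iterations. Covariates
are centered internally; the Breslow baseline cumulative hazard
$\hat\Lambda_0(t)$ (increments $d_j/\sum_{i\in R(t_j)} e^{\hat\beta^\top x_i}$,
Efron-weighted under Efron ties) is rescaled back to $x = 0$. The
proportional-hazards assumption is checked by a Grambsch–Therneau style
score test on scaled Schoenfeld residuals; the default time transform
is the left-continuous Kaplan–Meier scale, the convention of the
field's standard diagnostic, with identity and rank transforms
available.

Phase II scores each test-arm patient against the Phase-I model. With
$\hat\Lambda_i = \hat\Lambda_0(t_i)e^{\hat\beta^\top x_i}$ the expected
event count by the patient's follow-up time, the default ("mean")
score is the standardized martingale residual

$$U_i = \frac{\delta_i - \hat\Lambda_i}{\sqrt{\hat\Lambda_i}},$$

positive when survival is worse than predicted. A second-moment
("variance") score $V_i = (M_i^2 - \hat\Lambda_i)/\sqrt{2\hat\Lambda_i^2}$
is available behind `chart_config(component = "variance")` for
monitoring excess risk variability — the signature of a nonzero
random-effect (frailty) variance. The published family of charts this
implements leaves its exact score weighting to references that do not
print it; the mean component is the default here because the procedure
is explicitly described as monitoring per-case cumulative hazard, which
the martingale form captures directly. The scores are smoothed as
$Z_t = \lambda U_t + (1-\lambda)Z_{t-1}$, $Z_0 = z_0 = 0$, with
$\lambda = 0.1$ by default — the standard small-shift EWMA choice; the
motivating analysis does not state its value.

### Score conventions at the edges

* A case censored before the first Phase-I event time has
  $\hat\Lambda_i = 0$ and scores exactly 0.
* Follow-up beyond the baseline's support uses the last baseline value
  (with a warning): the Phase-I model simply has no information there.
* The standardizing denominator is floored at the baseline's **first
  increment** (scaled by the case's relative risk $e^{\hat\beta^\top x_i}$).
  A step baseline is exactly zero before its first event time, so a
  test-arm death there would otherwise be divided by the bare guard
  $\varepsilon = 10^{-8}$ and score $\sim 10^4$, dominating the chart
  for the next several dozen cases. The first increment is the finest
  risk the baseline can resolve, which makes it the natural floor; the
  $\varepsilon$ guard is retained underneath.

### Control limits

The in-control mean of $U_i$ is **not** zero: the standardizing weight
$1/\sqrt{\hat\Lambda_i}$ is correlated with the residual. For a fully
observed case the expected count at the event time is approximately
$\mathrm{Exp}(1)$, giving
$E[U] \approx E[(1-E)/\sqrt{E}] = \sqrt{\pi}/2 \approx 0.886$, pulled
down somewhat by censoring. The chart therefore centers its limits on
the EWMA's exact in-control mean path
$c(t) = \hat\mu_U + (z_0 - \hat\mu_U)(1-\lambda)^t$, and the score
distribution's strong right skew (an early death can score up to
$\sim\sqrt{n}$; an unexpected survivor only mildly negative) means one
symmetric multiplier would spend the whole false-alarm budget on the
high side. Both were confirmed empirically during development: limits
centered at $z_0$ with a symmetric multiplier left the low (improved
survival) side with power *below* the false-alarm rate under a
hazard-halving shift. The limits are therefore

$$L_l(t) = c(t) - L_l\,\hat\sigma_U\,w(t), \qquad
  L_u(t) = c(t) + L_u\,\hat\sigma_U\,w(t), \qquad
  w(t) = \sqrt{\tfrac{\lambda}{2-\lambda}\bigl(1-(1-\lambda)^{2t}\bigr)},$$

time-varying (exact EWMA variance inflation — constant asymptotic
limits over-signal on early cases), with $L_l, L_u$ chosen as the
$1-\alpha/2$ Monte-Carlo quantiles of the standardized per-side
deviations across `calibration_reps` in-control sequences simulated
from the fitted Phase-I model itself (covariates resampled from the
Phase-I arm, event times drawn by piecewise-constant inversion of the
Breslow baseline). The per-case false-alarm target is
$\alpha = 0.005$ — one expected false alarm per 200 monitored cases,
matching a test arm of 234 — split evenly between the sides.
Calibration and any validation or power study consume disjoint
substreams of one user seed, so they are independently reproducible.

## 2. Biomarker identification and validation

For each marker the candidate cut-points are the observed values whose
split leaves at least `minprop` (default 0.1, the cut-point tool
convention) of patients *and* at least one event on each side; the
selected cut maximizes the absolute standardized log-rank statistic
$|O - E|/\sqrt{V}$, ties broken toward the smaller value, and "high"
means strictly greater than the cut. No selection-adjusted p-value is
attached to the maximum itself — the maximally selected statistic is
not $\chi^2_1$, and this package deliberately reports none (a
documented limitation); inference instead rests on the interaction
model and resampling:

* **Interaction model.** Cox regression with treatment, marker class,
  their product, and (by default) the ECOG/extent-of-disease/pain
  adjustment covariates — the analysis is described as multivariable;
  an unadjusted option exists. Within-class treatment hazard ratios
  and Kaplan–Meier medians per arm accompany the interaction term.
* **Bootstrap stability.** Patients are resampled with replacement `B`
  times; the cut-point stays **fixed** (the wording of the motivating
  analysis: resamples are "divided based on the cut-point"), the
  interaction model is refit, and the proportion of replicates with
  interaction $p < 0.05$ is reported, with replicates losing an
  arm-by-class cell skipped and tallied. Re-estimating the cut per
  replicate is available as a stricter option.
* **Subgroup charts.** The full two-phase chart is rerun inside each
  marker class — Phase-I refit on the class's control patients
  (requiring a configurable minimum of 10 control events), limits
  recalibrated for the class's test-arm size. Recalibration per
  subgroup is the default because the subgroup baselines differ;
  reusing global limits would mis-state the subgroup false-alarm rate.
* No multiplicity adjustment is applied across markers' interaction
  tests by default (mirroring the motivating analysis); `bh_adjust()`
  is exported and `summary(fit, bh = TRUE)` applies the
  Benjamini–Hochberg step-up within a multivariable fit's covariate
  p-values, which is how the screening stage reports adjusted values.

## 3. The synthetic-cohort generator

`sim_config()` defaults define the reference study conditions: arms of
246/234; age $\sim N(64, 11^2)$ years; male with probability 0.533;
ECOG limited-activity 0.81; distant metastasis 0.733; pain intensity
$100\cdot\mathrm{Beta}(0.9, 2.4)$ (right-skewed on $[0,100]$, median
$\approx 22$, quartiles $\approx 9$–41); fifteen log-normal biomarkers
at plausible assay scales with $\sigma_{\log} = 1$. Event times follow
a Weibull proportional-hazards model
$h_0(t) = \lambda_w k t^{k-1}$ with $k = 1.2$ and $\lambda_w = 0.0715$,
solved once numerically so the control-arm median overall survival is
$\approx 5.9$ months under the default covariate mix; prognostic
log-hazard ratios are $\log 0.521$ (ECOG), $\log 2.054$ (extent of
disease) and $\log 1.004$ per pain point, and the treatment main
effect $-1.2\log(6.24/5.91) \approx -0.065$ reproduces 6.24- vs
5.91-month arm medians. Censoring is administrative at 36 months plus
an independent 10% chance of uniform early censoring, yielding the
high event fraction typical of this disease. Interactions are
threshold (step) effects applied to treatment-arm patients on one side
of a true quantile cut — matching the dichotomized analysis the
pipeline performs; a smooth alternative can be emulated by stacking
several small threshold effects.

What the generator does **not** emulate: assay measurement error and
batch effects, marker–marker and marker–covariate correlation,
enrollment-time drift, and the true (unpublished) marker marginals —
log-normality is an assumption. Tests passing on these cohorts
therefore certify the *procedure* (calibration, recovery, error rates
under the assumed structure), not distributional robustness on any
particular real dataset.

## 4. Numerical choices and degenerate inputs

* Ties: Efron default, Breslow selectable; both available everywhere a
  fit occurs, and the martingale-residual identity $\sum_i M_i = 0$
  holds exactly under both.
* Non-convergence, constant covariates, exact collinearity, empty risk
  sets, and coefficient divergence (monotone likelihood, $|\beta| > 25$)
  are errors with named diagnostics, not warnings.
* `fisher_exact_2x2` uses the "sum of probabilities no larger than the
  observed table" two-sided rule — exact two-sided conventions differ,
  and this is the one mainstream software uses. `mann_whitney_u` is
  exact below a combined $n$ of 50 without ties (the threshold is
  configurable; the motivating analysis does not state which form it
  used) and a tie-corrected normal approximation otherwise; completely
  tied samples return $p = 1$.
* Monitoring order is dataset row order; an enrollment order, if it
  differs, is the user's responsibility to encode in the row order.
* The cut-point search requires non-constant markers and at least one
  valid candidate; bootstrap replicates that lose a cell are skipped
  and counted rather than silently dropped.
* One user-facing seed expands into fixed substreams (covariates,
  biomarkers, event times, censoring, calibration, validation), all
  kept inside 32-bit integer range.

## 5. Problem sizes used by the test suite

The suite exercises every stage at desk scale, chosen so the full run
completes in about a minute while keeping Monte-Carlo error well inside
each test's tolerance: oracle-equivalence on dozens of small random
cohorts; null calibrations at 400–1000 replicates; coverage and
recovery at $n = 400$–500 with 40–200 replicates; chart calibration at
500 in-control sequences of 234 cases validated on 200 fresh
sequences; the acceptance script raises that to 1500 calibration and
500 validation sequences to tighten the estimate of the in-control
signal rate. The generator's default arm sizes and effect values are
never changed by tests — they *are* the reference conditions.

## 6. Known limitations

* The published chart family's exact weighted-score statistic is not
  printed in its sources; the standardized martingale form is this
  package's explicit, documented choice, with the variance component
  as an option. Whether the published limits were constant or
  time-varying is likewise unstated; time-varying is implemented.
* No selection-adjusted inference for the maximally selected cut-point.
* No CUSUM/Shewhart variants, no frailty-model fitting, no
  time-varying-coefficient or stratified Cox fitting.
* Real cohorts enter only through the documented CSV schema;
  complete-case handling of missing biomarkers is the default policy.
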