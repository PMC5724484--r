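---
title: "Dynamic risk prediction from repeated biomarker measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic risk prediction from repeated biomarker measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cardiovascular-style risk scores are usually built from a single baseline
measurement of each risk factor. When a predictor such as systolic blood
pressure (SBP) is volatile and measured with error, a single measurement
both dilutes the estimated hazard ratio (regression dilution) and throws
away whatever information the trajectory carries. This package implements
and compares the standard family of remedies on a common survival
backbone, and evaluates them with *dynamic* prediction metrics: at a
prediction time $t_p$, among subjects still at risk, how well does each
model predict events in the window $[t_p, t_p + L)$?

## Models

All models are proportional-hazards models of the form

$$ h_i(t) = h_0(t)\, \exp\{\psi_i(t)^\top \alpha + Z_i^\top \gamma\}, $$

differing only in how the time-varying predictor $\psi_i(t)$ is built from
the intermittent, error-prone measurements $X_i(t_{i0}), \dots,
X_i(t_{im_i})$:

* **BCF** (baseline carried forward): $\psi_i(t) = X_i(0)$ for all $t$.
  The convention behind most deployed risk scores.
* **LOCF** (last observation carried forward): the most recent
  measurement, updated at each visit.
* **CA** (cumulative average): the running mean of all measurements so
  far; averaging damps the measurement error. An exponentially weighted
  variant (`track_ewma()`) interpolates between CA and LOCF.
* **ORC** (ordinary regression calibration): a random-intercept
  random-slope mixed model
  $X_i(t) = \beta_0 + \beta_1 t + b_{0i} + b_{1i} t + \varepsilon_i(t)$
  is fitted once to all longitudinal data, and each subject's empirical
  Bayes pair $(\hat b_{0i}, \hat b_{1i})$ enters the hazard as two
  time-constant predictors with separate association parameters.
* **RRC** (risk-set regression calibration): like ORC, but the mixed model
  is refitted at successive update times using only subjects still at
  risk and only their past measurements, so the plug-in effects change
  over follow-up and never peek at the future.
* **Joint model**: the longitudinal and survival likelihoods are maximised
  simultaneously, linked by the shared random effects
  ($h_i(t \mid b) = h_0(t)\exp\{\alpha_0 b_{0i} + \alpha_1 b_{1i} +
  Z_i^\top\gamma\}$), integrating over $b$ rather than plugging in a point
  estimate.

Because every $\psi_i$ is constant given the information available at
$t_p$, the $L$-year risk has the closed form

$$ P_{iL}(t_p) = 1 - \left[\frac{\hat S_0(t_p + L)}{\hat S_0(t_p)}
\right]^{\exp(\hat\psi_i^\top \hat\alpha + Z_i^\top\hat\gamma)} , $$

which is why the package's survival fits are fully parametric (an
unspecified Cox baseline would not give $\hat S_0$ in closed form, so the
Cox partial likelihood is deliberately not implemented).

## Estimation machinery and numerical choices

**Counting-process episodes.** Time-varying predictors are handled by
splitting follow-up $(0, T^*_i]$ at each track change-point
(`episode_split()`). Intervals are half-open $(\text{start},
\text{stop}]$, the event sits at the final stop, and a measurement at
time $t$ changes the hazard's covariate just *after* $t$
(predictability) while remaining usable for a prediction made *at* $t$.
Measurements recorded at or after $T^*_i$ are dropped on construction: an
at-event measurement cannot inform a predictable hazard, and how ties
between measurement and event times were handled in the motivating cohort
is not recorded, so the package takes the conservative side.

**Baselines.** Exponential ($H_0(t) = \lambda t$), Weibull
($\log H_0 = \gamma_0 + \gamma_1 \log t$), and a restricted cubic spline
on $\log H_0(t)$ against $\log t$ (the Royston–Parmar flexible parametric
family), with internal knots at tertiles of the uncensored log event
times and linearity beyond the boundary knots. With no internal knots the
spline family *is* the Weibull, which the tests exploit as an exact
nested-family check. The exponential family is fitted through the
standard Poisson-GLM identity for piecewise-exponential likelihoods;
the other families by direct maximisation (BFGS, relative tolerance
1e-12), with a non-monotone fitted cumulative hazard reported as a
diagnostic failure rather than silently accepted. The simulation study
uses the exponential family throughout — it is the generating family, and
the bias/coverage questions concern measurement-error handling, not
baseline flexibility; the spline baseline exists for real cohorts, where
`fit_ph()` accepts any episode data.

**Mixed model.** `fit_lmm()` maximises the marginal Gaussian likelihood
(ML, not REML, so two-stage plug-ins and the joint fit maximise
comparable objectives) over $(\log\sigma_0, \log\sigma_1,
\operatorname{atanh}\rho, \log\sigma_\varepsilon)$ with the fixed effects
profiled out in closed form; subjects sharing a measurement-time pattern
share one Cholesky factorisation. Empirical Bayes effects use the exact
conditional-mean formula at any time cutoff. Boundary fits (a variance
collapsing to zero) are flagged, not clamped. One structural caveat
deserves emphasis: with only two distinct visit times the four variance
parameters sit on a likelihood ridge — the 2x2 marginal covariance of
the two measurements (three free moments) is identified, but its
decomposition into intercept/slope variances, correlation and residual
variance is not, and neither are the empirical Bayes pairs derived from
it. The first risk-set refit (baseline + first repeat) lives exactly in
this regime, as any implementation of the scheme must, so the
association coefficient fitted to those early plug-ins depends on which
ridge point the optimiser reaches; published values of that coefficient
are similarly tied to the fitting software's internal resolution.
Refits with three or more visit times are fully identified.

**Joint model.** The marginal likelihood integrates the product of the
Gaussian longitudinal density, the survival density
$h(T^*\mid b)^\delta \exp\{-H(T^*\mid b)\}$ and the random-effect prior
over $\mathbb{R}^2$ by adaptive Gauss–Hermite quadrature: each subject's
integrand is re-centred at its posterior mode (found by a damped,
vectorised 2-D Newton iteration — the log-integrand is strictly concave
for these baselines) and scaled by the mode curvature. The default is 9
points per dimension; the tests verify that moving to 15 points changes
the log-likelihood by less than $10^{-4}$ per subject, so the default is
converged rather than assumed. The optimiser starts from the two-stage
(ORC) estimates, which stabilises and shortens the search; standard
errors come from the numerically differentiated observed information.
The likelihood itself is checked against dense-grid 2-D integration on
tiny cohorts to $10^{-6}$.

**Empirical Bayes prediction under the joint model.** For subjects in the
estimation sample, `eb_random_effects()` uses each subject's full
likelihood contribution — all measurements and the event/censoring
outcome. This is deliberate: it is exactly what produces the estimation-
sample over-optimism the evaluation layer is designed to expose. Honest
predictions come from the validation-by-censoring protocol
(`make_validation_copy()`), where held-out subjects' records are
truncated just after $t_p$ (offset $10^{-6}$ years, small enough to add
no meaningful exposure but keeping them inside every risk set at $t_p$
under the strict convention), so the same code path then conditions only
on survival to $t_p$ and past measurements. No special-casing.

**Evaluation.** The windowed C-index follows the displayed definition:
events at $t_i \in [t_p, t_p + L]$ (closed right endpoint, matching the
concordance sum even though the risk formula's window is half-open — the
boundary has probability zero under continuous time), risk sets with the
$\geq$ convention so the failing subject is in its own risk set, ties
counted one half; simultaneous events enter each other's risk-set terms
exactly as the formula states. Standard errors are leave-one-subject-out
jackknives, computed by increment bookkeeping rather than re-enumeration;
for differences in C the jackknife is paired, which captures the strong
correlation between two models evaluated on the same subjects. The IPCW
Brier score weights by the Kaplan–Meier estimate of the censoring
distribution fitted on the at-risk subset (subjects censored inside the
window get weight zero); its reported SE treats the weights as fixed.
Calibration tables group subjects by quantiles of predicted risk and
compare group-mean predicted risk with one minus the within-group
Kaplan–Meier survivor at $t_p+L$, administratively censoring at the
window end; tied predictions collapse groups with a warning.

**Risk-set calibration details.** The package implements the
computationally convenient refit-at-each-visit scheme (refits keyed to
repeat visits, each using subjects still at risk who attended that
visit). Before the first update time no honest refit exists; the hazard
fit still needs a covariate value on $(0, \tau_1]$ for every subject, so
that segment carries a baseline-only empirical Bayes estimate under the
first refit's parameters (out-of-sample for subjects who never reach an
update time, and flagged as such). Predictions, by contrast, are simply
unavailable before the first update — `psi_at()` refuses them — because a
plug-in built from one measurement under a model fitted to others' futures
would not be a risk-set-calibrated prediction. A full
refit-at-every-event-time scheme can be had by passing a dense
`update_times` grid, at proportional cost.

## The synthetic cohort generator

`simulate_cohort()` draws from the same joint model the methods assume:
biomarker trajectories $x_{ij} = (\beta_0 + b_{0i}) + (\beta_1 +
b_{1i}) t_{ij} + \varepsilon_{ij}$ observed at visits 0, 3, 6, 9 years;
an exponential hazard $\lambda \exp(\alpha_0 b_{0i} + \alpha_1 b_{1i})$;
administrative censoring at 15 years; visits at or after the end of
follow-up unobserved (event-dependent truncation of the longitudinal
record — the feature that biases ordinary regression calibration). The
four stock scenarios (`scenario_parameters()`) emulate an SBP-like
marker: mean 120 mmHg rising 0.3 mmHg/year, between-person SDs 15 mmHg
and 1 mmHg/year (5 in scenarios 2–4), within-person SD 10 mmHg,
intercept–slope correlation −0.2 (0 in scenario 4), baseline rate
5/1000 person-years (0.06 in scenario 3), $\alpha_0 = 0.035$ (hazard
ratio 1.69 per SD of level), $\alpha_1 = 0.15$ (1.16 per SD of slope in
scenario 1, 2.12 in scenarios 2–4). Under these parameters the
15-year cumulative incidence in scenarios 1–2 is about 7% by direct
calculation — the random-number stream draws effects, then errors visit
by visit, then event times, so extending the visit schedule does not
perturb earlier draws.

What the generator does *not* emulate: covariate-dependent visit
schedules, dropout other than through the event or administrative
censoring, non-linear trajectories, treatment effects on the biomarker,
or competing risks. Tests passing on these cohorts therefore demonstrate
correctness of the estimators under the assumed model and the relative
behaviour of the seven fits, not robustness to the many ways real
cohort data deviate from it.

## The simulation study

`run_study()` loops scenarios and replicates: each replicate simulates a
cohort, fits the true-random-effects reference plus the six models,
records association estimates with Wald intervals, and (optionally)
computes estimation-sample dynamic C-indices and the
validation-by-censoring evaluation, in which a random subsample is
censored just after each prediction time, every model is refitted, and
held-out subjects' predictions are scored against their withheld
outcomes. Per-replicate seeds derive from the master seed by a
counter-based map, so any replicate can be reproduced in isolation and
results do not depend on evaluation order. Model failures within a
replicate are recorded and excluded from that cell's summary rather than
aborting the run.

Default problem sizes are reduced relative to the full design (5000
subjects, 200 replicates, 2000-subject validation copies): the stock
configuration uses 2000 subjects and 50 replicates, and the package's own
built-in checks use 1500–5000 subjects and 20–50 replicates with
Monte-Carlo error bands scaled accordingly. These sizes were chosen so a
complete run fits comfortably on a single CPU while keeping each
published contrast (bias pattern, coverage collapse, over-optimism,
repeat-measure gains) well outside its Monte-Carlo noise. One caveat
observed in development: the joint model's slope association carries a
finite-sample bias that shrinks roughly with the event count, so
reduced-scale runs reproduce the full-scale bias only up to that scaling.

## Known limitations

* No left truncation/delayed entry, interval censoring, competing risks,
  stratified or time-varying-coefficient baselines, or frailties.
* Joint fits support exponential and Weibull baselines; the spline
  baseline is currently available to the two-stage models only.
* One biomarker; the mixed model is fixed at random intercept + slope.
* Harrell-type concordance is used as published; censoring-robust
  variants (IPCW concordance) are out of scope.
* The Brier-score SE ignores the variability of the estimated censoring
  distribution.

## A worked example

```{r, eval = FALSE}
library(repeatrisk)

sim <- simulate_cohort(scenario_parameters(1), n = 2000, seed = 11)
x <- sim$data

# cumulative-average model
eps <- episode_split(x, track_ca(x))
fit <- fit_ph(eps, covariates = "biomarker")
tidy(fit)

# 5-year risks from year 9 and their discrimination
ps <- psi_at(track_ca(x), 9)
pr <- predict_risk(fit, ps[ps$subject_id %in% risk_set(x, 9), ], 9, 5)
dynamic_cindex(pr, x$survival, 9, 5)

# the full reduced-scale study
res <- run_study(study_config(scenarios = 1, n = 2000, replicates = 50,
                              seed = 1))
res$bias_coverage
autoplot(res, "cindex")
```
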