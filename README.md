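# repeatrisk

Dynamic survival risk prediction from intermittently measured, error-prone
biomarkers — and the machinery to find out whether modelling the repeats
actually helps.

## The problem

Clinical risk scores (10-year cardiovascular risk and its relatives) are
typically fitted to a single baseline measurement of each predictor. For a
volatile marker like systolic blood pressure, the measurement at hand is a
noisy snapshot of the underlying level, so the fitted log-hazard ratio is
attenuated (regression dilution) and any information in the trajectory is
discarded. A cohort with repeat visits offers several escalating remedies,
and this package implements all of them on one proportional-hazards
backbone

```
h_i(t) = h0(t) * exp( psi_i(t)' alpha + Z_i' gamma )
```

where `psi_i(t)` is built from subject i's measurement history by one of:

| model | `psi_i(t)` |
|---|---|
| BCF   | baseline value, carried forward |
| LOCF  | last observed value |
| CA    | running (cumulative) mean; EWMA variant available |
| ORC   | empirical Bayes `(b0_i, b1_i)` from one mixed model on all data |
| RRC   | same, refitted at successive times on subjects still at risk, past data only |
| joint | shared-random-effects joint longitudinal-survival model (adaptive Gauss-Hermite) |

All of these give a time-constant linear predictor at a prediction time
`t_p`, so the `L`-year risk for a subject still at risk is the closed form
`1 - [S0(t_p+L)/S0(t_p)]^exp(lp)`. Baselines are fully parametric:
exponential, Weibull, or restricted cubic splines on the log cumulative
hazard (Royston-Parmar).

The evaluation layer is dynamic: windowed Harrell C-index with jackknife
standard errors (and paired jackknife for differences against a reference
model), IPCW Brier scores, decile calibration tables, and a
validation-by-censoring protocol that censors a random subsample just
after `t_p`, refits every model, and scores the held-out subjects against
their withheld outcomes — the honest alternative to evaluating a joint
model on the data whose events it has already seen.

A fully parameterised simulation study (four stock scenarios emulating an
SBP-like marker) reproduces the published bias/coverage contrasts between
the seven fits (the six above plus a true-random-effects reference) and
the dynamic discrimination curves, without any external data.

## Worked example

```r
library(repeatrisk)

sim <- simulate_cohort(scenario_parameters(1), n = 2000, seed = 11)
x <- sim$data
x
#> <longsurv> cohort: 2000 subjects, 7753 measurements, 180 events

eps <- episode_split(x, track_ca(x))     # cumulative-average model
fit <- fit_ph(eps, covariates = "biomarker")
tidy(fit)
#> # A tibble: 2 × 5
#>   term       estimate std_error conf_low conf_high
#>   <chr>         <dbl>     <dbl>    <dbl>     <dbl>
#> 1 biomarker    0.0300   0.00467   0.0209    0.0392
#> 2 log_lambda  -8.80     0.604    -9.99     -7.62

ps <- psi_at(track_ca(x), 9)             # predictors usable at year 9
pr <- predict_risk(fit, ps[ps$subject_id %in% risk_set(x, 9), ],
                   t_p = 9, L = 5)
dynamic_cindex(pr, x$survival, t_p = 9, L = 5)
#> # A tibble: 1 × 7
#>   metric   t_p     L value     se n_at_risk n_events_in_window
#>   <chr>  <dbl> <dbl> <dbl>  <dbl>     <int>              <int>
#> 1 cindex     9     5 0.639 0.0423      1880                 48
```

The biomarker coefficient 0.030 sits between the attenuated
baseline-carried-forward value (0.026 on this same cohort) and the
generating `alpha0 = 0.035` — the cumulative average has partially
corrected the regression dilution. `fit_joint(x)` estimates the
association on the latent effects directly and recovers `alpha0` without
that attenuation.

The full study loop (all models, all scenarios, validation copies) is one
call:

```r
res <- run_study(study_config(scenarios = 1, n = 2000, replicates = 50,
                              eval_validation = TRUE, seed = 1))
res$bias_coverage
autoplot(res, "cindex")
```

A thin CLI for the same operations lives in `inst/cli/repeatrisk.R`
(`simulate` and `study` subcommands).

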