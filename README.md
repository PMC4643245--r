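# climsurv

Climate-window survival analysis: how far back, and with what weights,
do daily minimum temperature (MinT) and diurnal temperature range
(DTR = MaxT − MinT) affect mortality?

`climsurv` is for ecologists and biostatisticians analysing daily-resolution
survival data from organisms exposed to natural weather — e.g. birds in
outdoor aviaries — where the covariate of interest is not "today's
temperature" but an unknown weighted history of it. The package:

- collapses a daily climate series into a single time-dependent covariate
  through a **three-parameter Weibull lag-weight function**
  `w(t) ∝ (k/λ)((t−θ)/λ)^(k−1) exp(−((t−θ)/λ)^k)` over lags `t = 1..T`
  (the preceding day is lag 1), normalised to sum to 1;
- estimates the window parameters by **profiling the AICc of a
  counting-process Cox model** — daily `(start, stop]` intervals, delayed
  entry, Efron ties, cluster-robust (aviary) variance — over (shape,
  scale, location) with multi-start Nelder–Mead;
- compares windows across variables (**swap test**: re-weight one variable
  by the other's window and measure the AICc penalty) and across
  treatment groups;
- runs **all-subsets AICc model selection** (`dredge`) under marginality,
  with ΔAICc ≤ 4 presentation, Akaike weights and per-term support;
- reports treatment-dependent **DTR × MinT hazard surfaces**, conditional
  DTR effects at a reference MinT, and a **photoperiod confound check**;
- ships a first-class **synthetic-data module**: seasonal AR(1) climate,
  staggered-entry cohorts in aviaries nested within a foraging-cost
  treatment, and mortality generated from a known lagged-climate hazard
  `p(day) = 1 − exp(−h0 e^η)` — the ground truth every estimator test
  is checked against.

## Worked example

Simulate a cohort whose mortality is driven by a short MinT window
(80% of weight within 5 days, hazard ratio 0.85 per °C) and a long DTR
window (80% within ~80 days, hazard ratio 1.8 per °C), then recover the
structure:

```r
library(climsurv)

climate <- simulate_climate(climate_sim_config(n_days = 365 * 3 + 125, seed = 1))
schedule <- entry_schedule_periodic(600, first_frac = 0.5, start_day = 121,
                                    interval = 45, n_batches = 16)
roster <- simulate_cohort(cohort_sim_config(schedule, seed = 1), nrow(climate))
truth <- true_hazard_model(
  8e-4,
  coef = list(dtr = log(1.8), mint = log(0.85), dtr_mint = log(0.97)),
  mint_window = weibull_window(shape = 1, scale = 3, location = 0, max_lag = 120),
  dtr_window  = weibull_window(shape = 1.5, scale = 65, location = 0, max_lag = 120))
events <- simulate_survival(climate, roster, truth, max_follow_up = 365 * 3, seed = 1)

windows <- estimate_windows(events, climate, restarts = 3, maxit = 150, seed = 1)
windows$mint
#> Window search (mint): profile AICc 2999.892
#> Weibull lag window: shape = 2.222, scale = 1.764 d, location = 4.963e-11 d, T = 120 d
#>   cumulative weight reaches 50% / 80% / 100% at lag 2 / 2 / 8 days
windows$dtr
#> Window search (dtr): profile AICc 3004.203
#> Weibull lag window: shape = 2.742, scale = 54.54 d, location = 5.677e-09 d, T = 120 d
#>   cumulative weight reaches 50% / 80% / 100% at lag 48 / 65 / 120 days

swap_window_test(events, climate, windows, "dtr")$delta_aicc
#> [1] 53.6     # weighting DTR by the MinT window costs 53.6 AICc:
               # the two variables act on clearly different timescales

wd <- build_weighted_covariate(climate$dtr, windows$dtr$window)
wm <- build_weighted_covariate(climate$mint, windows$mint$window)
ivl <- expand_to_intervals(events, list(dtr = wd, mint = wm), burn_in = 120)
tab <- dredge(ivl, cox_model_spec(c("DTR", "MinT", "DTR:MinT", "AgeStart")))
within_delta(tab, 4)
#> AICc model selection: 4 models (global: DTR + MinT + DTR:MinT + AgeStart)
#>   model   DTR  MinT DTR:MinT AgeStart df     AICc delta_aicc weight
#> 1     1 1.746 0.863       NA       NA  2 2999.328      0.000  0.320
#> 2     2 1.745 0.863       NA    0.862  3 2999.829      0.501  0.249
#> 3     3 1.760 0.868    0.987       NA  3 2999.892      0.564  0.242
#> 4     4 1.759 0.868    0.987    0.861  4 3000.388      1.060  0.189
```

Reading the output: the recovered MinT window concentrates its weight in
the first couple of days and the DTR window spreads it over ~2 months —
the generating short/long contrast. The best model's hazard ratios, 1.75
per °C weighted DTR and 0.86 per °C weighted MinT, sit on top of the
generating values 1.8 and 0.85; the weak generating interaction
(HR 0.97) is, correctly, not forced into the top model. Hazard-ratio
columns are on the per-°C scale of the mean-centered weighted covariates,
so `hazard_ratio_percent(1.75)` ≈ a 75% increase in daily mortality per
°C of (weighted) DTR. With an interaction in the model,
`conditional_dtr_effect(fit, mint_value = 6)` gives the DTR hazard ratio
on days with weighted MinT of 6 °C, and
`hazard_surface(fit, ivl, context = ...)` evaluates the full relative
hazard surface masked to the observed covariate range.

A one-shot driver (`run_pipeline()`, or the CLI in `inst/cli/climsurv`:
`simulate`, `run-all`, …) chains reading the climate/cohort CSVs, window
estimation, per-treatment dredge tables, swap tests, hazard surfaces,
the photoperiod check, and a manifest with input hashes and seeds.

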