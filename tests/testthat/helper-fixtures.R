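# Shared fixtures, built in code.  Sizes are deliberately small: the
# deep statistical checks live in test-acceptance.R.

# short climate record: 2 years + window burn-in
fix_climate <- function(seed = 11, n_days = 365 * 2 + 125) {
  simulate_climate(climate_sim_config(n_days = n_days, seed = seed))
}

# small cohort with staggered entry across the climate record
fix_cohort <- function(climate, n = 120, seed = 11) {
  sched <- entry_schedule_periodic(n, first_frac = 0.5, start_day = 121L,
                                   interval = 60L, n_batches = 6L)
  simulate_cohort(cohort_sim_config(sched, seed = seed), nrow(climate))
}

# climate-free truth: moderate baseline so events are plentiful at small n
fix_truth_null <- function(h0 = 2e-3) {
  true_hazard_model(h0, coef = list(),
                    mint_window = weibull_window(1, 0.68, 0, 120L),
                    dtr_window = weibull_window(1.5, 65, 0, 120L))
}

# truth with clear climate effects and distinct windows, no age
# interactions: the canonical recovery world.  Short MinT window with 80%
# of its weight within 5 lags (days_to_fraction(0.8) = 5) and long DTR
# window with 80% within ~90 lags (days_to_fraction(0.8) = 89).
fix_truth_climate <- function(h0 = 8e-4) {
  true_hazard_model(h0,
                    coef = list(dtr = log(1.8), mint = log(0.85)),
                    mint_window = weibull_window(1, 3, 0, 120L),
                    dtr_window = weibull_window(1.5, 65, 0, 120L))
}

# a tiny hand-checkable interval table: 5 rows, 2 untied events
# id start stop event  wdtr  wmint
#  1   0    1     0     0.0   0.5
#  1   1    2     1     0.0  -0.5    <- event at t=2, risk set rows 2,3,4
#  2   0    2     0     1.0   0.2
#  3   1    3     1    -1.0   0.1    <- event at t=3, risk set row 4 only
#  4   3    4     0    -1.0  -0.3
fix_toy_intervals <- function() {
  d <- data.table::data.table(
    id = c(1L, 1L, 2L, 3L, 4L),
    start = c(0, 1, 0, 1, 3),
    stop = c(1, 2, 2, 3, 4),
    event = c(0L, 1L, 0L, 1L, 0L),
    cluster = c(1L, 1L, 1L, 2L, 2L),
    day = 1L,
    wdtr = c(0, 0, 1, -1, -1),
    wmint = c(0.5, -0.5, 0.2, 0.1, -0.3),
    agestart = 0, sqrtage = 0, brood = 0, sex_num = 0)
  data.table::setattr(d, "class", c("cohort_intervals", class(d)))
  d
}

# brute-force Efron partial log likelihood: direct risk-set enumeration,
# independent of the C++ engine
brute_loglik <- function(beta, X, start, stop, event) {
  eta <- as.numeric(X %*% beta)
  ll <- 0
  for (t in sort(unique(stop[event == 1]))) {
    dead <- which(event == 1 & stop == t)
    risk <- which(start < t & stop >= t)
    k <- length(dead)
    r <- exp(eta[risk]); rd <- exp(eta[dead])
    ll <- ll + sum(eta[dead])
    for (j in seq_len(k) - 1) ll <- ll - log(sum(r) - (j / k) * sum(rd))
  }
  ll
}
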