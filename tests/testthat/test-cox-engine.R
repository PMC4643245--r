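test_that("expand_to_intervals builds one row per at-risk day", {
  clim <- fix_climate(seed = 4)
  wd <- build_weighted_covariate(clim$dtr, weibull_window(1.5, 30, 0, 120))
  wm <- build_weighted_covariate(clim$mint, weibull_window(1, 1, 0, 120))
  weighted <- list(dtr = wd, mint = wm)

  # one individual, at risk 10 days beyond a 30-day burn-in, no event
  ev1 <- data.frame(id = 1L, entry_day = 200L, exit_day = 240L, event = 0L,
                    age_entry = 1, foraging = "easy", brood = "small",
                    aviary = 1L, sex = "f")
  class(ev1) <- c("cohort_events", "data.frame")
  ivl <- expand_to_intervals(ev1, weighted, burn_in = 30L)
  expect_equal(nrow(ivl), 10L)
  expect_true(all(ivl$event == 0L))
  expect_equal(ivl$stop, 31:40)
  expect_equal(ivl$stop - ivl$start, rep(1, 10))

  # death on the exit day: final row carries event = 1 at stop = follow-up
  ev2 <- ev1; ev2$event <- 1L
  ivl2 <- expand_to_intervals(ev2, weighted, burn_in = 30L)
  expect_equal(sum(ivl2$event), 1L)
  expect_equal(ivl2$stop[which(ivl2$event == 1L)], 40)

  # three birds, staggered entry: rows = at-risk days past the burn-in.
  # follow-ups are 110, 90 and 20 d; the third bird dies inside the
  # 30-day burn-in, so it (and its event) is excluded entirely
  ev3 <- data.frame(id = 1:3, entry_day = c(150L, 200L, 250L),
                    exit_day = c(260L, 290L, 270L), event = c(1L, 0L, 1L),
                    age_entry = c(0.5, 1, 2), foraging = "easy",
                    brood = "small", aviary = 1L, sex = "f")
  class(ev3) <- c("cohort_events", "data.frame")
  ivl3 <- expand_to_intervals(ev3, weighted, burn_in = 30L)
  expect_equal(nrow(ivl3), (110 - 30) + (90 - 30))
  expect_equal(sum(ivl3$event), 1L)

  # covariates are centered over bird-days and the constants recorded
  ctr <- attr(ivl3, "centers")
  expect_equal(mean(ivl3$wdtr), 0, tolerance = 1e-12)
  expect_equal(mean(ivl3$wmint), 0, tolerance = 1e-12)
  expect_gt(ctr[["dtr"]], 0)

  # an individual dying within the burn-in contributes nothing
  ev4 <- rbind(ev3, data.frame(id = 4L, entry_day = 200L, exit_day = 210L,
                               event = 1L, age_entry = 1, foraging = "easy",
                               brood = "small", aviary = 2L, sex = "f"))
  class(ev4) <- c("cohort_events", "data.frame")
  expect_equal(nrow(expand_to_intervals(ev4, weighted, burn_in = 30L)),
               nrow(ivl3))

  # covariate gaps raise an explicit burn-in error
  ev5 <- ev1; ev5$entry_day <- 100L; ev5$exit_day <- 160L
  class(ev5) <- c("cohort_events", "data.frame")
  expect_error(expand_to_intervals(ev5, weighted, burn_in = 10L),
               "undefined at calendar day")

  # age timescale encodes delayed entry
  ivl_age <- expand_to_intervals(ev3, weighted, burn_in = 30L,
                                 timescale = "age")
  expect_equal(ivl_age$stop - ivl_age$start, rep(1, nrow(ivl_age)))
  expect_true(all(ivl_age$start >= 0.5 * 365.25))
})

test_that("partial_loglik matches hand-enumerated risk sets", {
  d <- fix_toy_intervals()
  spec <- cox_model_spec(c("DTR", "MinT"))

  # beta = 0: each event contributes -log(risk-set size)
  # event at t=2: risk = rows with start < 2 <= stop -> rows 2, 3, 4 (m=3)
  # event at t=3: risk = row 4 only (m=1)
  expect_equal(partial_loglik(c(0, 0), d, spec), -log(3) - log(1),
               tolerance = 1e-12)

  # no events: loglik is exactly 0
  d0 <- fix_toy_intervals(); d0$event <- 0L
  expect_equal(partial_loglik(c(0.3, -0.2), d0, spec), 0)

  # arbitrary beta vs the brute-force oracle
  X <- cbind(d$wdtr, d$wmint)
  for (b in list(c(0.5, 0), c(-1, 2), c(0.3, -0.7)))
    expect_equal(partial_loglik(b, d, spec),
                 brute_loglik(b, X, d$start, d$stop, d$event),
                 tolerance = 1e-12)
  expect_error(partial_loglik(c(Inf, 0), d, spec), "finite")
})

test_that("partial_loglik handles ties exactly like the Efron oracle", {
  set.seed(71)
  n <- 60
  d <- data.table::data.table(
    id = 1:n, start = sample(0:3, n, TRUE))
  d[, stop := start + sample(1:5, n, TRUE)]
  d[, `:=`(event = rbinom(n, 1, 0.5), cluster = 1L, day = 1L,
           wdtr = rnorm(n), wmint = rnorm(n), agestart = 0, sqrtage = 0,
           brood = 0, sex_num = 0)]
  data.table::setattr(d, "class", c("cohort_intervals", class(d)))
  spec <- cox_model_spec(c("DTR", "MinT"))
  X <- cbind(d$wdtr, d$wmint)
  for (b in list(c(0, 0), c(0.4, -0.6)))
    expect_equal(partial_loglik(b, d, spec),
                 brute_loglik(b, X, d$start, d$stop, d$event),
                 tolerance = 1e-10)
})

test_that("fit_cox agrees with an independent survival implementation", {
  skip_if_not_installed("survival")
  set.seed(42)
  n <- 500
  d <- data.table::data.table(id = 1:n, start = sample(0:5, n, TRUE))
  d[, stop := start + sample(1:10, n, TRUE)]
  d[, `:=`(event = rbinom(n, 1, 0.3), cluster = sample(1:8, n, TRUE),
           day = 1L, wdtr = rnorm(n), wmint = rbinom(n, 1, 0.5),
           agestart = runif(n), sqrtage = 0, brood = 0, sex_num = 0)]
  data.table::setattr(d, "class", c("cohort_intervals", class(d)))
  fit <- fit_cox(d, cox_model_spec(c("DTR", "MinT", "AgeStart")))

  cf <- suppressWarnings(survival::coxph(
    survival::Surv(start, stop, event) ~ wdtr + wmint + agestart +
      survival::cluster(cluster),
    data = d, ties = "efron",
    control = survival::coxph.control(eps = 1e-12, iter.max = 50)))
  expect_equal(unname(fit$coefficients), unname(coef(cf)), tolerance = 1e-6)
  expect_equal(fit$loglik, cf$loglik[2], tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(sqrt(diag(cf$naive.var))),
               tolerance = 1e-6)
  expect_equal(unname(fit$robust_se), unname(sqrt(diag(cf$var))),
               tolerance = 1e-4)
  # hazard ratio identity
  expect_identical(fit$hazard_ratios, exp(fit$coefficients))
})

test_that("fit_cox recovers a known coefficient and is invariant", {
  clim <- fix_climate(seed = 31)
  sched <- entry_schedule_periodic(300, 0.5, 121, 45, 8)
  ros <- simulate_cohort(cohort_sim_config(sched, seed = 31), nrow(clim))
  truth <- fix_truth_climate(1.2e-3)
  ev <- simulate_survival(clim, ros, truth, 600, seed = 31)
  wd <- build_weighted_covariate(clim$dtr, truth$dtr_window)
  wm <- build_weighted_covariate(clim$mint, truth$mint_window)
  ivl <- expand_to_intervals(ev, list(dtr = wd, mint = wm), burn_in = 120L)
  spec <- cox_model_spec(c("DTR", "MinT"))
  fit <- fit_cox(ivl, spec)
  # simulation consistency: within 3 SE of the generating value
  expect_lt(abs(fit$coefficients[["DTR"]] - log(1.8)),
            3 * fit$se[["DTR"]])
  expect_lt(abs(fit$coefficients[["MinT"]] - log(0.85)),
            3 * fit$se[["MinT"]])

  # permuting rows changes nothing
  perm <- sample(nrow(ivl))
  ivl_p <- ivl[perm]
  data.table::setattr(ivl_p, "class", class(ivl))
  data.table::setattr(ivl_p, "centers", attr(ivl, "centers"))
  fit_p <- fit_cox(ivl_p, spec)
  expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-10)
  expect_equal(fit_p$aicc, fit$aicc, tolerance = 1e-10)

  # duplicating every individual under shifted ids: exactly invariant
  # under Breslow; under Efron the doubled tie counts change the
  # within-tie discount, so invariance is only asymptotic -- assert a
  # tight but not exact agreement
  ivl2 <- data.table::rbindlist(list(ivl, data.table::copy(ivl)[
    , id := id + max(ivl$id)]))
  data.table::setattr(ivl2, "class", class(ivl))
  data.table::setattr(ivl2, "centers", attr(ivl, "centers"))
  fit2 <- fit_cox(ivl2, spec)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 5e-3)

  # adding a constant to a covariate column leaves hazard ratios unchanged
  ivl3 <- data.table::copy(ivl)[, wdtr := wdtr + 5]
  data.table::setattr(ivl3, "class", class(ivl))
  fit3 <- fit_cox(ivl3, spec)
  expect_equal(fit3$hazard_ratios, fit$hazard_ratios, tolerance = 1e-6)

  # rank deficiency names the aliased term (Brood is constant 0 in the toy)
  toy <- fix_toy_intervals()
  expect_error(fit_cox(toy, cox_model_spec(c("DTR", "Brood"))), "Brood")
})

test_that("Efron and Breslow agree when no event times are tied", {
  skip_if_not_installed("survival")
  set.seed(9)
  n <- 40
  d <- data.table::data.table(
    id = 1:n, start = 0, stop = sort(runif(n, 1, 100)),  # unique times
    event = rbinom(n, 1, 0.5), cluster = 1L, day = 1L,
    wdtr = rnorm(n), wmint = rnorm(n), agestart = 0, sqrtage = 0,
    brood = 0, sex_num = 0)
  data.table::setattr(d, "class", c("cohort_intervals", class(d)))
  fit <- fit_cox(d, cox_model_spec(c("DTR", "MinT")))
  cb <- suppressWarnings(survival::coxph(
    survival::Surv(start, stop, event) ~ wdtr + wmint,
    data = d, ties = "breslow",
    control = survival::coxph.control(eps = 1e-12)))
  expect_equal(unname(fit$coefficients), unname(coef(cb)), tolerance = 1e-6)
})

test_that("aicc, lr_test and akaike_weights do their arithmetic", {
  expect_equal(aicc(-50, 3, 50), 106 + 24 / 46, tolerance = 1e-12)
  expect_equal(aicc(-50, 0, 10), 100)
  expect_lt(abs(aicc(-10, 5, 1e9) - (20 + 10)), 1e-6)   # AICc -> AIC
  expect_error(aicc(-50, 5, 6), "n > p")

  # chi-square tail identities
  expect_equal(stats::pchisq(3.841, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
  # X2 = 10.411 on 1 df sits at p ~ 0.00125
  expect_equal(stats::pchisq(10.411, 1, lower.tail = FALSE), 0.00125,
               tolerance = 3e-3)
  d <- fix_toy_intervals()
  f_full <- fit_cox(d, cox_model_spec(c("DTR", "MinT")))
  f_red <- fit_cox(d, cox_model_spec("DTR"))
  lr <- lr_test(f_full, f_red)
  expect_equal(lr$statistic, 2 * (f_full$loglik - f_red$loglik),
               tolerance = 1e-10)
  expect_equal(lr$df, 1)
  expect_equal(lr$p.value,
               stats::pchisq(lr$statistic, 1, lower.tail = FALSE))
  # identical models: X2 = 0, p = 1
  lr0 <- lr_test(f_full, f_full)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p.value, 1)
  expect_error(lr_test(f_red, f_full), "not nested")

  expect_equal(akaike_weights(100), 1)
  expect_equal(akaike_weights(c(100, 102)),
               c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(akaike_weights(rep(7, 5)), rep(0.2, 5))
  expect_equal(sum(akaike_weights(c(310.2, 311.7, 313.4, 320))), 1,
               tolerance = 1e-12)
  expect_error(akaike_weights(numeric(0)), "empty")
})

test_that("model spec enforces marginality and validates terms", {
  expect_error(cox_model_spec(c("DTR:MinT")), "marginality")
  expect_error(cox_model_spec(c("DTR", "DTR:MinT")), "marginality")
  expect_silent(cox_model_spec(c("DTR", "MinT", "DTR:MinT")))
  # age interactions need only the non-age parent
  expect_silent(cox_model_spec(c("DTR", "DTR:Age")))
  expect_error(cox_model_spec("Banana"), "unknown")
})
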