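test_that("simulate_climate honours its configuration contract", {
  # noise-free, amplitude-free series is exactly constant
  cfg0 <- climate_sim_config(n_days = 100, mean_mint = 6,
                             seasonal_amplitude_mint = 0,
                             seasonal_amplitude_dtr = 0,
                             noise_sd_mint = 0, noise_sd_dtr = 0, seed = 1)
  clim0 <- simulate_climate(cfg0)
  expect_equal(clim0$mint, rep(6, 100))
  expect_equal(clim0$dtr, rep(8, 100))

  # determinism: same seed, byte-identical
  cfg <- climate_sim_config(n_days = 400, seed = 99)
  expect_identical(simulate_climate(cfg), simulate_climate(cfg))
  # different seed differs
  expect_false(identical(
    simulate_climate(cfg)$mint,
    simulate_climate(climate_sim_config(n_days = 400, seed = 100))$mint))

  # MaxT - MinT = DTR exactly, DTR never negative
  clim <- simulate_climate(climate_sim_config(n_days = 2000, seed = 3))
  expect_identical(clim$maxt - clim$mint, clim$dtr)
  expect_true(all(clim$dtr >= 0))

  expect_error(climate_sim_config(n_days = 0), "n_days")
  expect_error(climate_sim_config(ar_coefficient = 1), "ar_coefficient")
  expect_error(climate_sim_config(noise_sd_mint = -1), "noise_sd_mint")
})

test_that("simulated climate reproduces configured moments", {
  # 10 years; mean within 3 SE of 6; residual lag-1 autocorrelation ~ 0.6
  n <- 3650
  cfg <- climate_sim_config(n_days = n, mean_mint = 6,
                            seasonal_amplitude_mint = 8,
                            ar_coefficient = 0.6, noise_sd_mint = 3,
                            seed = 42)
  clim <- simulate_climate(cfg)
  # SE of the mean of an AR(1) with stationary sd s: s/sqrt(n) * sqrt((1+ar)/(1-ar))
  se <- 3 / sqrt(n) * sqrt(1.6 / 0.4)
  expect_lt(abs(mean(clim$mint) - 6), 3 * se)
  doy <- as.POSIXlt(clim$date)$yday + 1
  resid <- clim$mint - (6 + 8 * sin(2 * pi * (doy - cfg$phase_mint) / 365.25))
  ac1 <- stats::cor(resid[-1], resid[-n])
  expect_lt(abs(ac1 - 0.6), 0.05)
})

test_that("climate CSV round-trips and validates", {
  clim <- fix_climate(seed = 2, n_days = 150)
  tf <- tempfile(fileext = ".csv")
  write_climate_csv(clim, tf)
  back <- read_climate_csv(tf)
  expect_equal(back$mint, clim$mint, tolerance = 1e-12)
  expect_equal(back$date, clim$date)

  bad <- utils::read.csv(tf)
  bad$dtr_c <- bad$dtr_c + 1
  tf2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, tf2, row.names = FALSE)
  expect_error(read_climate_csv(tf2), "MaxT")
  bad$dtr_c <- NULL
  utils::write.csv(bad, tf2, row.names = FALSE)
  expect_error(read_climate_csv(tf2), "dtr_c")
})

test_that("simulate_cohort fills the requested design", {
  sched <- data.frame(day = 121L, count = 4L)
  r <- simulate_cohort(cohort_sim_config(sched, seed = 1))
  expect_equal(nrow(r), 4L)
  expect_true(all(r$entry_day == 121L))

  # crossed design: every foraging x brood cell non-empty at modest n
  clim <- fix_climate(seed = 1)
  r2 <- fix_cohort(clim, n = 60, seed = 1)
  expect_true(all(table(r2$foraging, r2$brood) > 0))
  # aviaries nest within foraging
  expect_true(all(table(r2$aviary, r2$foraging) %in%
                    c(0, table(r2$aviary))))

  # conservation: per-aviary counts sum to the requested total
  sched3 <- entry_schedule_periodic(476, first_frac = 0.4, start_day = 121,
                                    interval = 90, n_batches = 12)
  r3 <- simulate_cohort(cohort_sim_config(sched3, seed = 5))
  expect_equal(sum(table(r3$aviary)), 476L)
  expect_equal(nrow(r3), 476L)

  # entry beyond the climate span is a range error
  expect_error(
    simulate_cohort(cohort_sim_config(data.frame(day = 900, count = 2)),
                    n_days_climate = 800),
    "beyond the climate span")

  # determinism
  cfgc <- cohort_sim_config(sched3, seed = 5)
  expect_identical(simulate_cohort(cfgc), simulate_cohort(cfgc))
})

test_that("simulate_survival obeys closed-form constant-hazard expectations", {
  # h0 = 0: nobody dies
  clim <- fix_climate(seed = 3)
  roster <- fix_cohort(clim, n = 40, seed = 3)
  ev0 <- simulate_survival(clim, roster, fix_truth_null(0), 200, seed = 1)
  expect_equal(sum(ev0$event), 0L)
  expect_true(all(ev0$exit_day - ev0$entry_day <= 200))

  # constant hazard: deaths within binomial 99% bounds of the expectation.
  # p_day = 1 - exp(-h0); over k days P(death) = 1 - (1-p)^k; run at
  # 600 x 600 rather than 1000 x 1000 to keep the suite fast
  h0 <- -log(1 - 0.001)           # daily death probability exactly 0.001
  n <- 600; k <- 600
  clim2 <- simulate_climate(climate_sim_config(n_days = 125 + k, seed = 8))
  sched <- data.frame(day = 121L, count = n)
  ros <- simulate_cohort(cohort_sim_config(sched, seed = 8), nrow(clim2))
  ev <- simulate_survival(clim2, ros, fix_truth_null(h0), k, seed = 8)
  p_death <- 1 - 0.999^k                     # k at-risk days each
  expect_gte(sum(ev$event), qbinom(0.005, n, p_death))
  expect_lte(sum(ev$event), qbinom(0.995, n, p_death))

  # burn-in precondition: entries need a full window of climate history
  early <- data.frame(day = 50L, count = 3L)
  ros_e <- simulate_cohort(cohort_sim_config(early, seed = 1), nrow(clim2))
  expect_error(simulate_survival(clim2, ros_e, fix_truth_null(), 100, 1),
               "burn-in")

  # determinism given the mortality seed
  ev_a <- simulate_survival(clim2, ros, fix_truth_null(h0), k, seed = 4)
  ev_b <- simulate_survival(clim2, ros, fix_truth_null(h0), k, seed = 4)
  expect_identical(ev_a, ev_b)
})

test_that("a positive weighted-DTR coefficient orders survival by exposure", {
  clim <- simulate_climate(climate_sim_config(n_days = 365 * 2 + 125, seed = 21))
  sched <- entry_schedule_periodic(400, 0.5, 121, 45, 8)
  ros <- simulate_cohort(cohort_sim_config(sched, seed = 21), nrow(clim))
  truth <- true_hazard_model(1e-3, coef = list(dtr = 0.6),
                             mint_window = weibull_window(1, 0.68, 0, 120),
                             dtr_window = weibull_window(1.5, 30, 0, 120))
  ev <- simulate_survival(clim, ros, truth, 500, seed = 21)
  # exposure: mean weighted DTR over each individual's at-risk days
  wd <- build_weighted_covariate(clim$dtr, truth$dtr_window)
  expo <- vapply(seq_len(nrow(ev)), function(i)
    mean(wd[(ev$entry_day[i] + 1):ev$exit_day[i]]), 0)
  ter <- cut(expo, quantile(expo, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
             labels = FALSE)
  # compare death fraction in top vs bottom exposure tertile
  expect_gte(mean(ev$event[ter == 3]), mean(ev$event[ter == 1]))
})

test_that("cohort CSV round-trips through the pipeline dialect", {
  clim <- fix_climate(seed = 6)
  ros <- fix_cohort(clim, n = 30, seed = 6)
  ev <- simulate_survival(clim, ros, fix_truth_null(), 300, seed = 6)
  tf <- tempfile(fileext = ".csv")
  write_cohort_csv(ev, tf)
  back <- read_cohort_csv(tf, clim)
  expect_equal(back$entry_day, ev$entry_day)
  expect_equal(back$exit_day, ev$exit_day)
  expect_equal(back$event, ev$event)
  expect_equal(back$age_entry, ev$age_entry, tolerance = 1e-12)

  # schema validation names the missing column
  x <- utils::read.csv(tf); x$event <- NULL
  tf2 <- tempfile(fileext = ".csv")
  utils::write.csv(x, tf2, row.names = FALSE)
  expect_error(read_cohort_csv(tf2, clim), "event")
})
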