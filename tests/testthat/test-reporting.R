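test_that("hazard_ratio_percent is the (hr - 1) * 100 transform", {
  expect_equal(hazard_ratio_percent(1.0), 0)
  expect_equal(hazard_ratio_percent(2.0), 100)
  expect_error(hazard_ratio_percent(0), "positive")
  expect_error(hazard_ratio_percent(-1), "positive")
  # monotone in the coefficient
  b <- seq(-1, 1, length.out = 11)
  expect_true(!is.unsorted(hazard_ratio_percent(exp(b))))
})

test_that("conditional_dtr_effect follows the interaction formula", {
  # synthetic fit object with known coefficients and centering
  fit <- structure(list(
    coefficients = c(DTR = log(1.36), MinT = log(0.89),
                     "DTR:MinT" = log(0.953)),
    hazard_ratios = exp(c(DTR = log(1.36), MinT = log(0.89),
                          "DTR:MinT" = log(0.953))),
    centers = c(dtr = 8, mint = 6)), class = "climsurv_cox")

  # at the centering constant: exactly the main-effect hazard ratio
  expect_equal(conditional_dtr_effect(fit, 6), 1.36, tolerance = 1e-12)
  # 10 degrees above center: direct evaluation of the formula
  expect_equal(conditional_dtr_effect(fit, 16),
               exp(log(1.36) + 10 * log(0.953)), tolerance = 1e-12)
  # no interaction coefficient: flat in MinT
  fit0 <- fit
  fit0$coefficients[["DTR:MinT"]] <- 0
  expect_equal(conditional_dtr_effect(fit0, -20),
               conditional_dtr_effect(fit0, 20), tolerance = 1e-12)

  fit_bad <- fit; fit_bad$coefficients <- fit$coefficients["MinT"]
  expect_error(conditional_dtr_effect(fit_bad, 6), "DTR")
})

test_that("hazard_surface evaluates exp(eta) relative to the reference", {
  ivl <- fix_toy_intervals()
  spec <- cox_model_spec(c("DTR", "MinT", "DTR:MinT"))
  # a hand-made fit: beta known, centers zero
  beta <- c(DTR = 0.2, MinT = -0.1, "DTR:MinT" = 0.05)
  fit <- structure(list(coefficients = beta, hazard_ratios = exp(beta),
                        centers = c(dtr = 0, mint = 0), spec = spec),
                   class = "climsurv_cox")
  surf <- hazard_surface(fit, ivl, context = list(),
                         dtr = c(-1, 0, 1), mint = c(-1, 0, 1))
  expect_equal(nrow(surf), 9L)
  # reference point: relative hazard exactly 1
  expect_equal(surf$rel_hazard[surf$dtr == 0 & surf$mint == 0], 1,
               tolerance = 1e-12)
  # direct evaluation on the 3x3 grid
  for (i in seq_len(9)) {
    eta <- 0.2 * surf$dtr[i] - 0.1 * surf$mint[i] +
      0.05 * surf$dtr[i] * surf$mint[i]
    expect_equal(surf$rel_hazard[i], exp(eta), tolerance = 1e-12)
  }
  expect_true(all(surf$rel_hazard > 0))

  # all-zero coefficients: flat surface of 1
  fit0 <- fit; fit0$coefficients[] <- 0
  surf0 <- hazard_surface(fit0, ivl, context = list(),
                          dtr = c(-1, 1), mint = c(-1, 1))
  expect_equal(surf0$rel_hazard, rep(1, 4))

  # monotone along DTR at fixed MinT when the conditional slope has one sign
  surf1 <- hazard_surface(fit, ivl, context = list(),
                          dtr = seq(-2, 2, 0.5), mint = 0)
  expect_true(!is.unsorted(surf1$rel_hazard))

  # missing context covariates are named
  spec2 <- cox_model_spec(c("DTR", "MinT", "DTR:MinT", "AgeStart"))
  fit2 <- fit
  fit2$coefficients <- c(beta, AgeStart = 0.2)
  fit2$spec <- spec2
  expect_error(hazard_surface(fit2, ivl, context = list(), dtr = 0, mint = 0),
               "age_start")
})

test_that("photoperiod matches an independent solar computation", {
  # equinox: about 12 h everywhere supported
  for (lat in c(-45, 0, 30, 53.217, 60))
    expect_lt(abs(photoperiod("2009-03-20", lat) - 12), 0.2)

  # independent oracle: the CBM day-of-year declination model (Forsythe
  # et al. 1995).  Solstices agree to well under a minute; mid-season the
  # CBM model's fixed-equinox phasing drifts by up to ~8 minutes, which
  # bounds the cross-check there.
  cbm_daylength <- function(date, lat) {
    J <- as.POSIXlt(as.Date(date))$yday + 1
    theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (J - 186)))
    decl <- asin(0.39795 * cos(theta))
    x <- -tan(lat * pi / 180) * tan(decl)
    (24 / pi) * acos(pmin(pmax(x, -1), 1))
  }
  for (d in c("2009-06-21", "2009-12-21"))
    expect_lt(abs(photoperiod(d, 53.217) - cbm_daylength(d, 53.217)),
              5 / 60)   # solstices: within 5 minutes
  for (d in c("2009-04-15", "2009-09-01"))
    expect_lt(abs(photoperiod(d, 53.217) - cbm_daylength(d, 53.217)),
              10 / 60)  # mid-season: within the CBM model's phase drift
  expect_error(photoperiod("2009-06-21", 70), "polar")
})

test_that("the photoperiod confound check runs and reports", {
  clim <- fix_climate(seed = 51)
  ros <- fix_cohort(clim, n = 150, seed = 51)
  truth <- fix_truth_climate(1.5e-3)
  ev <- simulate_survival(clim, ros, truth, 600, seed = 51)
  wd <- build_weighted_covariate(clim$dtr, truth$dtr_window)
  wm <- build_weighted_covariate(clim$mint, truth$mint_window)
  ivl <- expand_to_intervals(ev, list(dtr = wd, mint = wm), burn_in = 120L,
                             climate = clim)
  fit <- fit_cox(ivl, cox_model_spec(c("DTR", "MinT")))
  chk <- add_photoperiod_check(fit, ivl)
  expect_named(chk, c("lr", "delta_aicc", "coef_shift", "fit_with"))
  expect_gte(chk$lr$statistic, 0)
  expect_equal(chk$lr$df, 1)
  expect_true("Photoperiod" %in% names(chk$fit_with$coefficients))

  # intervals built without a climate table cannot run the check
  ivl2 <- expand_to_intervals(ev, list(dtr = wd, mint = wm), burn_in = 120L)
  expect_error(add_photoperiod_check(fit, ivl2), "photoperiod")
})
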