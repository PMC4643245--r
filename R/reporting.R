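#' Hazard ratio as percent change
#'
#' `(hr - 1) * 100`: a hazard ratio of 1.25 is a 25% increase in the
#' hazard per unit of the covariate.
#'
#' @param hr hazard ratio(s), > 0.
#' @return percent change(s).
#' @export
hazard_ratio_percent <- function(hr) {
  if (any(!is.finite(hr)) || any(hr <= 0))
    stop("hazard ratios must be positive", call. = FALSE)
  (hr - 1) * 100
}

#' Conditional DTR hazard ratio at a given MinT
#'
#' With a DTR x MinT interaction, the per-degree DTR hazard ratio depends
#' on MinT: `exp(b_DTR + b_DTRxMinT * (mint - center))`, where `center`
#' is the mean-centering constant of weighted MinT recorded in the fit.
#' At `mint` equal to the centering constant this is exactly the DTR
#' main-effect hazard ratio.
#'
#' @param fit a `climsurv_cox` containing `DTR` and `DTR:MinT` terms.
#' @param mint_value weighted MinT on the raw (uncentered) scale, deg C.
#' @return hazard ratio per deg C weighted DTR.
#' @export
conditional_dtr_effect <- function(fit, mint_value) {
  stopifnot(inherits(fit, "climsurv_cox"))
  need <- c("DTR", "DTR:MinT")
  miss <- setdiff(need, names(fit$coefficients))
  if (length(miss))
    stop("fit lacks required term(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ctr <- fit$centers[["mint"]]
  exp(fit$coefficients[["DTR"]] +
        fit$coefficients[["DTR:MinT"]] * (mint_value - ctr))
}

#' Relative hazard surface over weighted DTR and MinT
#'
#' Evaluates `exp(eta)` of a fitted model over a grid of weighted DTR and
#' MinT values (raw scale) for a fixed covariate context, relative to the
#' reference at which all centered covariates are zero.  Grid points
#' outside the central 95% of the observed joint range are masked.
#'
#' @param fit a `climsurv_cox`.
#' @param data the `cohort_intervals` the fit used (for the coverage
#'   mask).
#' @param context named list supplying every non-climate covariate the
#'   model needs, on natural scales: `age_start` (years), `age` (years),
#'   `brood` (0/1), `sex` (0/1), `photoperiod` (hours) as applicable.
#' @param dtr,mint grid vectors on the raw weighted scale; defaults span
#'   95% of the observed data.
#' @param n_grid grid resolution when `dtr` / `mint` are defaulted.
#' @return data.frame of class `hazard_surface`: `dtr`, `mint`,
#'   `rel_hazard`, `in_range`.
#' @export
hazard_surface <- function(fit, data, context, dtr = NULL, mint = NULL,
                           n_grid = 41L) {
  stopifnot(inherits(fit, "climsurv_cox"))
  ctr <- fit$centers
  obs_d <- data$wdtr + ctr[["dtr"]]
  obs_m <- data$wmint + ctr[["mint"]]
  rng <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  rd <- rng(obs_d); rm_ <- rng(obs_m)
  if (is.null(dtr)) dtr <- seq(rd[1L], rd[2L], length.out = n_grid)
  if (is.null(mint)) mint <- seq(rm_[1L], rm_[2L], length.out = n_grid)
  grid <- expand.grid(dtr = dtr, mint = mint)

  terms <- names(fit$coefficients)
  need_ctx <- character(0)
  if (any(grepl("Age$", terms) | terms %in% "AgeStart"))
    need_ctx <- c(need_ctx, if (any(terms %in% c("AgeStart", "AgeStart:Age")))
      "age_start", if (any(grepl(":Age$", terms))) "age")
  if (any(grepl("^Brood", terms))) need_ctx <- c(need_ctx, "brood")
  if ("Sex" %in% terms) need_ctx <- c(need_ctx, "sex")
  if ("Photoperiod" %in% terms) need_ctx <- c(need_ctx, "photoperiod")
  miss <- setdiff(unique(need_ctx), names(context))
  if (length(miss))
    stop("context is missing covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  d <- list(wdtr = grid$dtr - ctr[["dtr"]],
            wmint = grid$mint - ctr[["mint"]],
            agestart = context$age_start %||% 0,
            sqrtage = sqrt(context$age %||% 0),
            brood = context$brood %||% 0,
            sex_num = context$sex %||% 0,
            photoperiod = context$photoperiod %||% 0)
  bld <- term_builders()
  eta <- 0
  for (tm in terms) eta <- eta + fit$coefficients[[tm]] * bld[[tm]](d)
  # reference: all centered covariates zero, same context -> subtract the
  # context-only part so the surface is 1 at (centered DTR, MinT) = (0, 0)
  d0 <- d; d0$wdtr <- 0; d0$wmint <- 0
  eta0 <- 0
  for (tm in terms) eta0 <- eta0 + fit$coefficients[[tm]] * bld[[tm]](d0)
  out <- data.frame(grid,
                    rel_hazard = exp(eta - eta0),
                    in_range = grid$dtr >= rd[1L] & grid$dtr <= rd[2L] &
                      grid$mint >= rm_[1L] & grid$mint <= rm_[2L])
  class(out) <- c("hazard_surface", "data.frame")
  out
}

#' Daylength from the standard solar declination formula
#'
#' Geometric daylength (sun-centre horizon crossing, no refraction
#' correction) from the low-precision solar-position series: solar mean
#' longitude and anomaly advance the ecliptic longitude, declination
#' follows from the obliquity, and the hour angle at rise gives
#' `daylength = (24/pi) * acos(-tan(lat) tan(decl))`.  Accurate to about
#' a minute at temperate latitudes, which is more than a seasonal
#' confound covariate needs.
#'
#' @param date `Date` vector (or coercible).
#' @param latitude degrees north; must satisfy `abs(latitude) < 66.5`
#'   (the formula breaks down across the polar circles).
#' @return daylength in hours.
#' @export
photoperiod <- function(date, latitude = 53.217) {
  if (abs(latitude) >= 66.5)
    stop("latitude beyond the polar circle is not supported", call. = FALSE)
  n <- as.numeric(as.Date(date) - as.Date("2000-01-01")) + 0.5
  deg <- pi / 180
  L <- (280.460 + 0.9856474 * n) %% 360          # mean longitude
  g <- (357.528 + 0.9856003 * n) %% 360          # mean anomaly
  lambda <- L + 1.915 * sin(g * deg) + 0.020 * sin(2 * g * deg)
  eps <- 23.439 - 0.0000004 * n                  # obliquity
  decl <- asin(sin(eps * deg) * sin(lambda * deg))
  x <- -tan(latitude * deg) * tan(decl)
  (24 / pi) * acos(pmin(pmax(x, -1), 1))
}

#' Does photoperiod explain the climate effect away?
#'
#' Adds daylength as a covariate to a fitted model and reports the
#' likelihood-ratio test, the AICc change, and how much the climate
#' coefficients move — the standard check that a seasonal confound, not
#' temperature itself, drives the hazard.
#'
#' @param fit a `climsurv_cox` (the best model of a selection table).
#' @param data the `cohort_intervals` the fit used; must carry a
#'   `photoperiod` column (pass `climate` to [expand_to_intervals()]).
#' @return list: `lr` (statistic, df, p), `delta_aicc`
#'   (AICc(with) - AICc(without); negative favours adding photoperiod),
#'   `coef_shift` (max absolute change of the climate coefficients),
#'   `fit_with`.
#' @export
add_photoperiod_check <- function(fit, data) {
  stopifnot(inherits(fit, "climsurv_cox"))
  if (!"photoperiod" %in% names(data))
    stop("'data' lacks a photoperiod column; rebuild intervals with a climate table",
         call. = FALSE)
  spec0 <- fit$spec
  if ("Photoperiod" %in% spec0$terms)
    stop("model already contains photoperiod", call. = FALSE)
  spec1 <- cox_model_spec(c(spec0$terms, "Photoperiod"),
                          timescale = spec0$timescale,
                          cluster = spec0$cluster, aicc_n = spec0$aicc_n)
  fit1 <- fit_cox(data, spec1, init = c(fit$coefficients, 0))
  lr <- lr_test(fit1, fit)
  clim <- intersect(c("DTR", "MinT", "DTR:MinT"), names(fit$coefficients))
  shift <- if (length(clim))
    max(abs(fit1$coefficients[clim] - fit$coefficients[clim])) else NA_real_
  list(lr = lr, delta_aicc = fit1$aicc - fit$aicc, coef_shift = shift,
       fit_with = fit1)
}
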