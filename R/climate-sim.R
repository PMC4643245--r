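#' Configuration for the climate simulator
#'
#' The generator emulates a temperate-zone daily weather record: minimum
#' temperature (MinT) and diurnal temperature range (DTR) each follow a
#' sinusoidal seasonal cycle plus stationary AR(1) noise.  Defaults mimic
#' a Dutch lowland station: annual mean MinT of 6 degrees C, winter trough
#' in mid January, and a DTR around 8 degrees C that peaks in late spring.
#'
#' `noise_sd_*` is the *stationary* standard deviation of the AR(1)
#' residual process (innovation SD is `noise_sd * sqrt(1 - ar^2)`), so the
#' marginal day-to-day spread does not change when `ar_coefficient` does.
#' DTR is kept non-negative by redrawing the day's innovation (not by
#' clipping), so the DTR distribution has no point mass at zero.
#'
#' @param n_days number of days to simulate.
#' @param mean_mint annual mean MinT (deg C).
#' @param seasonal_amplitude_mint half-range of the MinT seasonal cycle (deg C).
#' @param mean_dtr annual mean DTR (deg C).
#' @param seasonal_amplitude_dtr half-range of the DTR seasonal cycle (deg C).
#' @param ar_coefficient AR(1) coefficient in `[0, 1)`, shared by both series.
#' @param noise_sd_mint stationary SD of MinT residuals (deg C).
#' @param noise_sd_dtr stationary SD of DTR residuals (deg C).
#' @param mint_dtr_cor correlation between the MinT and DTR innovations.
#'   The cross-correlation of the two series is not pinned down by typical
#'   station summaries, so it is exposed as a parameter and defaults to 0.
#' @param start_date calendar date of day 1 (ISO string or `Date`).
#' @param phase_mint,phase_dtr day-of-year at which each seasonal sine
#'   crosses its mean going up; defaults put the MinT trough in mid
#'   January and the DTR peak in May.
#' @param seed integer seed for this layer's private RNG stream.
#' @return A validated list of class `climate_sim_config`.
#' @export
climate_sim_config <- function(n_days = 365L * 5L + 25L,
                               mean_mint = 6,
                               seasonal_amplitude_mint = 6,
                               mean_dtr = 8,
                               seasonal_amplitude_dtr = 2.5,
                               ar_coefficient = 0.7,
                               noise_sd_mint = 3,
                               noise_sd_dtr = 2.5,
                               mint_dtr_cor = 0,
                               start_date = "2008-01-01",
                               phase_mint = 105,
                               phase_dtr = 36,
                               seed = 1L) {
  cfg <- list(n_days = as.integer(n_days), mean_mint = mean_mint,
              seasonal_amplitude_mint = seasonal_amplitude_mint,
              mean_dtr = mean_dtr,
              seasonal_amplitude_dtr = seasonal_amplitude_dtr,
              ar_coefficient = ar_coefficient,
              noise_sd_mint = noise_sd_mint, noise_sd_dtr = noise_sd_dtr,
              mint_dtr_cor = mint_dtr_cor,
              start_date = as.Date(start_date),
              phase_mint = phase_mint, phase_dtr = phase_dtr,
              seed = as.integer(seed))
  chk <- function(ok, field, msg)
    if (!ok) stop(sprintf("invalid climate config field '%s': %s", field, msg),
                  call. = FALSE)
  chk(!is.na(cfg$n_days) && cfg$n_days >= 1L, "n_days", "must be >= 1")
  chk(is.finite(cfg$ar_coefficient) && cfg$ar_coefficient >= 0 &&
        cfg$ar_coefficient < 1, "ar_coefficient", "must be in [0, 1)")
  chk(is.finite(cfg$noise_sd_mint) && cfg$noise_sd_mint >= 0,
      "noise_sd_mint", "must be >= 0")
  chk(is.finite(cfg$noise_sd_dtr) && cfg$noise_sd_dtr >= 0,
      "noise_sd_dtr", "must be >= 0")
  chk(is.finite(cfg$mint_dtr_cor) && abs(cfg$mint_dtr_cor) <= 1,
      "mint_dtr_cor", "must be in [-1, 1]")
  chk(is.finite(cfg$mean_dtr) && cfg$mean_dtr >= 0, "mean_dtr", "must be >= 0")
  chk(!is.na(cfg$start_date), "start_date", "must parse as a date")
  class(cfg) <- "climate_sim_config"
  cfg
}

#' Simulate a daily climate series
#'
#' Draws MinT and DTR as seasonal sinusoids plus AR(1) noise and derives
#' MaxT as `MinT + DTR` (the identity holds exactly on every day).  DTR is
#' kept non-negative by redrawing the AR(1) innovation for offending days.
#' Output is byte-identical for identical configs (private RNG stream;
#' the caller's RNG state is untouched).
#'
#' @param config a [climate_sim_config()].
#' @return A `data.frame` of class `daily_climate` with columns
#'   `date`, `day` (1-based index), `mint`, `maxt`, `dtr`.
#' @export
simulate_climate <- function(config = climate_sim_config()) {
  stopifnot(inherits(config, "climate_sim_config"))
  n <- config$n_days
  with_seed(config$seed, "climate", {
  doy <- as.POSIXlt(config$start_date + (seq_len(n) - 1L))$yday + 1L
  seas <- function(mean, amp, phase)
    mean + amp * sin(2 * pi * (doy - phase) / 365.25)
  mu_mint <- seas(config$mean_mint, config$seasonal_amplitude_mint,
                  config$phase_mint)
  mu_dtr <- seas(config$mean_dtr, config$seasonal_amplitude_dtr,
                 config$phase_dtr)

  ar <- config$ar_coefficient
  innov_sd <- sqrt(1 - ar^2)   # unit stationary SD before scaling
  rho <- config$mint_dtr_cor
  z_m <- stats::rnorm(n)
  z_d_ind <- stats::rnorm(n)
  z_d <- rho * z_m + sqrt(1 - rho^2) * z_d_ind

  e_m <- numeric(n); e_d <- numeric(n)
  e_m[1L] <- z_m[1L]; e_d[1L] <- z_d[1L]
  for (i in seq_len(n)[-1L]) {
    e_m[i] <- ar * e_m[i - 1L] + innov_sd * z_m[i]
    e_d[i] <- ar * e_d[i - 1L] + innov_sd * z_d[i]
  }
  mint <- mu_mint + config$noise_sd_mint * e_m
  dtr <- mu_dtr + config$noise_sd_dtr * e_d

  # redraw innovations for days where DTR would be negative
  if (config$noise_sd_dtr > 0) {
    for (i in seq_len(n)) {
      tries <- 0L
      while (dtr[i] < 0 && tries < 1000L) {
        prev <- if (i > 1L) e_d[i - 1L] else 0
        innov <- if (i > 1L) innov_sd else 1
        e_d[i] <- ar * prev * (i > 1L) + innov * stats::rnorm(1L)
        dtr[i] <- mu_dtr[i] + config$noise_sd_dtr * e_d[i]
        tries <- tries + 1L
      }
      if (dtr[i] < 0) dtr[i] <- 0  # pathological config; keep invariant
    }
  } else {
    dtr <- pmax(dtr, 0)
  }

  maxt <- mint + dtr
  dtr <- maxt - mint   # re-derive so MaxT - MinT = DTR holds bit-exactly
  out <- data.frame(date = config$start_date + (seq_len(n) - 1L),
                    day = seq_len(n),
                    mint = mint, maxt = maxt, dtr = dtr)
  class(out) <- c("daily_climate", "data.frame")
  attr(out, "config") <- config
  out
  })
}

#' Write / read the daily climate CSV dialect
#'
#' Columns: `date` (ISO-8601), `mint_c`, `maxt_c`, `dtr_c`.
#'
#' @param climate a `daily_climate` data.frame.
#' @param path file path.
#' @return `path` invisibly; `read_climate_csv()` returns a
#'   `daily_climate`.
#' @export
write_climate_csv <- function(climate, path) {
  stopifnot(inherits(climate, "daily_climate"))
  utils::write.csv(
    data.frame(date = format(climate$date, "%Y-%m-%d"),
               mint_c = climate$mint, maxt_c = climate$maxt,
               dtr_c = climate$dtr),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "mint_c", "maxt_c", "dtr_c")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("climate CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(date = as.Date(x$date), day = seq_len(nrow(x)),
                    mint = x$mint_c, maxt = x$maxt_c, dtr = x$dtr_c)
  if (max(abs(out$maxt - out$mint - out$dtr)) > 1e-6)
    stop("climate CSV violates MaxT = MinT + DTR", call. = FALSE)
  class(out) <- c("daily_climate", "data.frame")
  out
}

# Evaluate `expr` under a private RNG stream derived from (seed, stream),
# restoring the caller's RNG state afterwards.  Keeps the climate / roster /
# mortality / search streams separate so one layer can be varied while the
# others stay fixed.
with_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  offset <- switch(stream, climate = 101L, roster = 211L, mortality = 307L,
                   search = 401L, 503L)
  # keep derived seeds well inside 32-bit range
  set.seed((as.integer(seed) %% 1000003L) * 1000L + offset)
  expr
}
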