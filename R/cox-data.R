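#' Expand a cohort to daily counting-process intervals
#'
#' Builds the (start, stop] risk-interval table of the counting-process
#' Cox model: one row per individual per at-risk day after the burn-in,
#' with time-dependent covariates evaluated at each day.  The burn-in
#' drops each individual's first `burn_in` days after entry, because the
#' lag-weighted climate covariate is undefined (or unrepresentative) until
#' enough outdoor exposure history exists.
#'
#' Weighted DTR and MinT are mean-centered over the included bird-days
#' (not over calendar days); the constants are recorded in the
#' `"centers"` attribute so hazard surfaces and conditional effects can be
#' mapped back to the raw scale.
#'
#' @param events a `cohort_events` table (entry/exit days, event flag,
#'   treatments).
#' @param weighted named list with day-level *uncentered* weighted series
#'   `dtr` and `mint` (from [build_weighted_covariate()]).
#' @param burn_in days excluded after each entry; defaults to the largest
#'   window length so all compared fits share one event set.
#' @param timescale `"study"` or `"age"` baseline time.
#' @param climate optional `daily_climate`; needed when a spec uses
#'   `Photoperiod` (dates) — pass with `latitude`.
#' @param latitude degrees north, for the photoperiod covariate.
#' @param center mean-center the weighted covariates (default TRUE).
#' @return A `data.table` of class `cohort_intervals` with columns `id`,
#'   `start`, `stop`, `event`, `cluster`, `day` (calendar day) and the
#'   covariate columns `wdtr`, `wmint`, `agestart`, `sqrtage`, `brood`,
#'   `sex_num` (and `photoperiod` when computable).  Attributes:
#'   `centers`, `timescale`, `burn_in`, `n_individuals`.
#' @export
expand_to_intervals <- function(events, weighted, burn_in = 120L,
                                timescale = c("study", "age"),
                                climate = NULL, latitude = 53.217,
                                center = TRUE) {
  timescale <- match.arg(timescale)
  stopifnot(is.data.frame(events),
            all(c("id", "entry_day", "exit_day", "event") %in% names(events)))
  if (!all(c("dtr", "mint") %in% names(weighted)))
    stop("'weighted' must contain day-level series 'dtr' and 'mint'",
         call. = FALSE)
  burn_in <- as.integer(burn_in)
  wdtr_day <- as.numeric(weighted$dtr)
  wmint_day <- as.numeric(weighted$mint)

  follow <- events$exit_day - events$entry_day       # days of follow-up
  n_at_risk <- pmax(0L, follow - burn_in)            # rows per individual
  keep <- which(n_at_risk > 0L)
  if (!length(keep))
    stop("no individual survives the burn-in; nothing to analyse",
         call. = FALSE)
  idx <- rep.int(keep, n_at_risk[keep])
  t_study <- sequence(n_at_risk[keep]) + burn_in     # study day of each row
  day <- events$entry_day[idx] + t_study             # calendar day
  if (max(day) > length(wdtr_day))
    stop("weighted covariates do not cover day ", max(day), call. = FALSE)
  wdtr <- wdtr_day[day]
  wmint <- wmint_day[day]
  if (anyNA(wdtr) || anyNA(wmint)) {
    first_bad <- day[which(is.na(wdtr) | is.na(wmint))[1L]]
    stop(sprintf("weighted covariate undefined at calendar day %d (window burn-in); increase burn_in or extend the climate record",
                 first_bad), call. = FALSE)
  }

  age <- events$age_entry[idx] + t_study / 365.25
  ev <- as.integer(t_study == follow[idx] & events$event[idx] == 1L)
  if (timescale == "study") {
    start <- as.numeric(t_study - 1L); stop_ <- as.numeric(t_study)
  } else {
    entry_age_days <- events$age_entry[idx] * 365.25
    start <- entry_age_days + (t_study - 1L); stop_ <- entry_age_days + t_study
  }

  out <- data.table::data.table(
    id = events$id[idx], start = start, stop = stop_, event = ev,
    cluster = if ("aviary" %in% names(events)) events$aviary[idx] else events$id[idx],
    day = day,
    wdtr = wdtr, wmint = wmint,
    agestart = events$age_entry[idx],
    sqrtage = sqrt(age),
    brood = if ("brood" %in% names(events))
      as.numeric(events$brood[idx] == "large") else 0,
    sex_num = if ("sex" %in% names(events) && !anyNA(events$sex))
      as.numeric(events$sex[idx] == "m") else 0,
    foraging = if ("foraging" %in% names(events))
      events$foraging[idx] else "all"
  )
  centers <- c(dtr = 0, mint = 0)
  if (isTRUE(center)) {
    centers <- c(dtr = mean(out$wdtr), mint = mean(out$wmint))
    out[, `:=`(wdtr = wdtr - centers[["dtr"]],
               wmint = wmint - centers[["mint"]])]
  }
  if (!is.null(climate))
    out[, photoperiod := photoperiod(climate$date[day], latitude)]
  data.table::setattr(out, "class",
                      c("cohort_intervals", class(out)))
  data.table::setattr(out, "centers", centers)
  data.table::setattr(out, "timescale", timescale)
  data.table::setattr(out, "burn_in", burn_in)
  data.table::setattr(out, "n_individuals", length(keep))
  out[]
}
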