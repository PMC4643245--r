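#' Configuration for the cohort simulator
#'
#' Emulates an aviary survival experiment: individuals enter in staggered
#' batches (the staggering is what makes calendar-day climate identifiable
#' against a time-in-study baseline), are housed in single-sex aviaries
#' nested within a two-level foraging-cost treatment, and carry a crossed
#' two-level developmental treatment (brood size).
#'
#' @param entry_schedule data.frame with columns `day` (calendar day index
#'   into the climate series) and `count`; see [entry_schedule_periodic()].
#' @param age_at_entry_range range (years) of the uniform age-at-entry draw.
#' @param n_aviaries number of aviaries; the first half are assigned the
#'   "easy" foraging treatment, the second half "hard", so aviaries nest
#'   within foraging level.
#' @param seed integer seed for this layer's private RNG stream.
#' @return A validated list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(entry_schedule,
                              age_at_entry_range = c(0.25, 2),
                              n_aviaries = 8L,
                              seed = 1L) {
  stopifnot(is.data.frame(entry_schedule),
            all(c("day", "count") %in% names(entry_schedule)))
  if (any(entry_schedule$count < 0) || sum(entry_schedule$count) < 1)
    stop("entry_schedule must request at least one individual", call. = FALSE)
  if (any(entry_schedule$day < 1))
    stop("entry days must be >= 1", call. = FALSE)
  n_aviaries <- as.integer(n_aviaries)
  if (n_aviaries < 2L || n_aviaries %% 2L != 0L)
    stop("'n_aviaries' must be an even integer >= 2 so aviaries nest within foraging level",
         call. = FALSE)
  if (length(age_at_entry_range) != 2L || diff(age_at_entry_range) < 0 ||
      age_at_entry_range[1L] < 0)
    stop("'age_at_entry_range' must be an increasing non-negative range",
         call. = FALSE)
  structure(list(entry_schedule = entry_schedule,
                 n_individuals = as.integer(sum(entry_schedule$count)),
                 age_at_entry_range = as.numeric(age_at_entry_range),
                 n_aviaries = n_aviaries, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Periodic entry schedule
#'
#' An initial batch at `start_day` followed by equal batches every
#' `interval` days, mirroring a colony where new birds are periodically
#' added to replace dead ones.
#'
#' @param n_total total number of individuals.
#' @param first_frac fraction entering in the initial batch.
#' @param start_day calendar day of the first batch (must leave enough
#'   climate history before it for the lag window: typically
#'   `max_lag + 1`).
#' @param interval days between subsequent batches.
#' @param n_batches number of follow-up batches.
#' @return data.frame with columns `day`, `count`.
#' @export
entry_schedule_periodic <- function(n_total, first_frac = 0.5,
                                    start_day = 121L, interval = 60L,
                                    n_batches = 10L) {
  n_first <- round(n_total * first_frac)
  rest <- n_total - n_first
  per <- rest %/% n_batches
  counts <- c(n_first, rep(per, n_batches))
  counts[n_batches + 1L] <- counts[n_batches + 1L] + (rest - per * n_batches)
  data.frame(day = as.integer(start_day + c(0L, seq_len(n_batches) * interval)),
             count = as.integer(counts))
}

#' Simulate a cohort roster
#'
#' @param config a [cohort_sim_config()].
#' @param n_days_climate optional length of the climate series; when given,
#'   entry days beyond it raise a range error.
#' @return data.frame of class `cohort_roster`: `id`, `entry_day`,
#'   `age_entry` (years), `foraging` ("easy"/"hard"), `brood`
#'   ("small"/"large"), `aviary` (integer), `sex` ("f"/"m").
#' @export
simulate_cohort <- function(config, n_days_climate = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  sched <- config$entry_schedule
  if (!is.null(n_days_climate) && any(sched$day > n_days_climate))
    stop(sprintf("entry day %d is beyond the climate span (%d days)",
                 max(sched$day), n_days_climate), call. = FALSE)
  n <- config$n_individuals
  with_seed(config$seed, "roster", {
    entry_day <- rep(sched$day, sched$count)
    age_entry <- stats::runif(n, config$age_at_entry_range[1L],
                              config$age_at_entry_range[2L])
    # aviaries nest within foraging: first half easy, second half hard;
    # individuals are spread round-robin within each foraging arm
    n_av <- config$n_aviaries
    half <- n_av %/% 2L
    forag <- rep(c("easy", "hard"), length.out = n)
    aviary <- integer(n)
    aviary[forag == "easy"] <- rep(seq_len(half),
                                   length.out = sum(forag == "easy"))
    aviary[forag == "hard"] <- rep(half + seq_len(half),
                                   length.out = sum(forag == "hard"))
    brood <- sample(c("small", "large"), n, replace = TRUE)
    sex <- c("f", "m")[(aviary %% 2L) + 1L]  # single-sex aviaries
    out <- data.frame(id = seq_len(n), entry_day = entry_day,
                      age_entry = age_entry,
                      foraging = forag, brood = brood,
                      aviary = aviary, sex = sex,
                      stringsAsFactors = FALSE)
    class(out) <- c("cohort_roster", "data.frame")
    out
  })
}

#' Ground-truth lagged-climate hazard model
#'
#' The generative model for the survival simulator: a constant baseline
#' daily hazard multiplied by `exp(eta)`, where `eta` is a linear
#' predictor over Weibull-weighted, mean-centered DTR and MinT, their
#' interaction, age at entry, sqrt(age) interactions and brood size.
#' Coefficients are log hazard ratios.  Per-foraging-treatment overrides
#' let the DTR x MinT interaction (or any other term) change sign between
#' treatments.
#'
#' @param baseline_daily_hazard baseline hazard per day, in `[0, 1)`.
#' @param coef named list of log hazard ratios; recognised names:
#'   `dtr`, `mint`, `dtr_mint`, `age_start`, `age_start_age`, `dtr_age`,
#'   `mint_age`, `brood`, `brood_dtr`, `brood_age`.  Missing names are 0.
#' @param mint_window,dtr_window [weibull_window()] objects defining the
#'   lag structure of each climate variable.
#' @param overrides named list (`easy` / `hard`) of coefficient lists that
#'   replace entries of `coef` within that foraging treatment.
#' @return A list of class `true_hazard_model`.
#' @export
true_hazard_model <- function(baseline_daily_hazard = 8e-4,
                              coef = list(),
                              mint_window = weibull_window(1, 0.68, 0, 120L),
                              dtr_window = weibull_window(1.5, 65, 0, 120L),
                              overrides = list()) {
  if (!is.numeric(baseline_daily_hazard) || baseline_daily_hazard < 0 ||
      baseline_daily_hazard >= 1)
    stop("'baseline_daily_hazard' must be in [0, 1)", call. = FALSE)
  known <- c("dtr", "mint", "dtr_mint", "age_start", "age_start_age",
             "dtr_age", "mint_age", "brood", "brood_dtr", "brood_age")
  bad <- setdiff(names(coef), known)
  if (length(bad))
    stop("unknown coefficient name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (ov in overrides) {
    bad <- setdiff(names(ov), known)
    if (length(bad))
      stop("unknown override coefficient name(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  stopifnot(inherits(mint_window, "weibull_window"),
            inherits(dtr_window, "weibull_window"))
  structure(list(baseline_daily_hazard = baseline_daily_hazard,
                 coef = coef, mint_window = mint_window,
                 dtr_window = dtr_window, overrides = overrides),
            class = "true_hazard_model")
}

#' Table-1-like default truth
#'
#' A ground truth shaped like zebra-finch colony findings: DTR
#' raises mortality, MinT lowers it slightly, the DTR x MinT interaction
#' is negative in the easy foraging environment and positive in the hard
#' one, the DTR effect wanes with age, and large broods cost survival in
#' the hard environment.  MinT acts within days, DTR over about three
#' months.
#'
#' @param baseline_daily_hazard baseline daily hazard.
#' @return A `true_hazard_model`.
#' @export
default_truth <- function(baseline_daily_hazard = 8e-4) {
  true_hazard_model(
    baseline_daily_hazard = baseline_daily_hazard,
    coef = list(dtr = log(1.36), mint = log(0.89), dtr_mint = log(0.953),
                age_start = log(1.25), dtr_age = log(0.74),
                mint_age = log(1.06)),
    overrides = list(
      hard = list(dtr = log(2.04), mint = log(0.88), dtr_mint = log(1.03),
                  age_start = log(1.34), dtr_age = log(0.50),
                  mint_age = log(1.05), brood = log(1.15))),
    mint_window = weibull_window(1, 0.68, 0, 120L),
    dtr_window = weibull_window(1.5, 65, 0, 120L)
  )
}

truth_coef <- function(truth, foraging) {
  known <- c("dtr", "mint", "dtr_mint", "age_start", "age_start_age",
             "dtr_age", "mint_age", "brood", "brood_dtr", "brood_age")
  b <- stats::setNames(numeric(length(known)), known)
  for (nm in names(truth$coef)) b[nm] <- truth$coef[[nm]]
  ov <- truth$overrides[[foraging]]
  for (nm in names(ov)) b[nm] <- ov[[nm]]
  b
}

#' Simulate mortality from a known lagged-climate hazard
#'
#' Each individual-day `d` after entry receives a death probability
#' `p(d) = 1 - exp(-h0 * exp(eta(d)))` (complementary log-log link, so the
#' daily discrete process converges to a proportional-hazards process as
#' the day length shrinks).  `eta(d)` is the truth's linear predictor on
#' Weibull-weighted, mean-centered climate covariates; the first Bernoulli
#' success is the death day and survivors are censored at
#' `max_follow_up` or the end of the climate record.
#'
#' @param climate a `daily_climate`.
#' @param roster a `cohort_roster`.
#' @param truth a [true_hazard_model()].
#' @param max_follow_up maximum days of follow-up per individual.
#' @param seed seed for the mortality RNG stream.
#' @return data.frame of class `cohort_events`: roster columns plus
#'   `exit_day`, `event` (1 death / 0 censored), `entry_date`, `exit_date`.
#'   The weighted covariate centering constants used by the generator are
#'   attached as attribute `centers`.
#' @export
simulate_survival <- function(climate, roster, truth,
                              max_follow_up = 5L * 365L, seed = 1L) {
  stopifnot(inherits(climate, "daily_climate"),
            inherits(roster, "cohort_roster"),
            inherits(truth, "true_hazard_model"))
  n_days <- nrow(climate)
  T_need <- max(truth$mint_window$max_lag, truth$dtr_window$max_lag)
  if (any(roster$entry_day < T_need))
    stop(sprintf("burn-in violation: entry day %d has fewer than %d days of climate history before it",
                 min(roster$entry_day), T_need), call. = FALSE)
  if (any(roster$entry_day >= n_days))
    stop("entry day at or beyond the end of the climate record", call. = FALSE)

  wd <- build_weighted_covariate(climate$dtr, truth$dtr_window, center = TRUE)
  wm <- build_weighted_covariate(climate$mint, truth$mint_window, center = TRUE)
  centers <- c(dtr = attr(wd, "center"), mint = attr(wm, "center"))
  h0 <- truth$baseline_daily_hazard

  n <- nrow(roster)
  exit_day <- integer(n)
  event <- integer(n)
  with_seed(seed, "mortality", {
    for (i in seq_len(n)) {
      d0 <- roster$entry_day[i]
      days <- seq.int(d0 + 1L, min(d0 + max_follow_up, n_days))
      if (h0 == 0) { exit_day[i] <- days[length(days)]; event[i] <- 0L; next }
      b <- truth_coef(truth, roster$foraging[i])
      age <- roster$age_entry[i] + (days - d0) / 365.25
      sage <- sqrt(age)
      broodL <- as.numeric(roster$brood[i] == "large")
      x_d <- wd[days]; x_m <- wm[days]
      eta <- b["dtr"] * x_d + b["mint"] * x_m + b["dtr_mint"] * x_d * x_m +
        b["age_start"] * roster$age_entry[i] +
        b["age_start_age"] * roster$age_entry[i] * sage +
        b["dtr_age"] * x_d * sage + b["mint_age"] * x_m * sage +
        b["brood"] * broodL + b["brood_dtr"] * broodL * x_d +
        b["brood_age"] * broodL * sage
      p <- 1 - exp(-h0 * exp(eta))
      u <- stats::runif(length(days))
      hit <- which(u < p)
      if (length(hit)) {
        exit_day[i] <- days[hit[1L]]
        event[i] <- 1L
      } else {
        exit_day[i] <- days[length(days)]
        event[i] <- 0L
      }
    }
  })
  out <- cbind(roster,
               data.frame(exit_day = exit_day, event = event,
                          entry_date = climate$date[roster$entry_day],
                          exit_date = climate$date[exit_day]))
  class(out) <- c("cohort_events", "data.frame")
  attr(out, "centers") <- centers
  out
}

#' Write / read the cohort CSV dialect
#'
#' Columns: `id`, `entry_date`, `exit_date`, `event`, `age_entry_years`,
#' `foraging`, `brood`, `aviary`, `sex`.
#'
#' @param events a `cohort_events` data.frame.
#' @param path file path.
#' @param climate a `daily_climate` used to map dates back to day indices
#'   when reading.
#' @return `path` invisibly; `read_cohort_csv()` returns a
#'   `cohort_events`.
#' @export
write_cohort_csv <- function(events, path) {
  stopifnot(inherits(events, "cohort_events"))
  utils::write.csv(
    data.frame(id = events$id,
               entry_date = format(events$entry_date, "%Y-%m-%d"),
               exit_date = format(events$exit_date, "%Y-%m-%d"),
               event = events$event,
               age_entry_years = events$age_entry,
               foraging = events$foraging, brood = events$brood,
               aviary = events$aviary, sex = events$sex),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, climate) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "entry_date", "exit_date", "event", "age_entry_years",
            "foraging", "brood", "aviary")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("cohort CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  day_of <- function(d) match(as.Date(d), climate$date)
  entry_day <- day_of(x$entry_date); exit_day <- day_of(x$exit_date)
  if (anyNA(entry_day) || anyNA(exit_day))
    stop("cohort CSV contains dates outside the climate record", call. = FALSE)
  out <- data.frame(id = x$id, entry_day = entry_day,
                    age_entry = x$age_entry_years,
                    foraging = x$foraging, brood = x$brood,
                    aviary = x$aviary,
                    sex = if ("sex" %in% names(x)) x$sex else NA_character_,
                    exit_day = exit_day, event = x$event,
                    entry_date = as.Date(x$entry_date),
                    exit_date = as.Date(x$exit_date),
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_events", "cohort_roster", "data.frame")
  out
}
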