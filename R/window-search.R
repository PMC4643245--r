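#' Window search configuration
#'
#' Controls the maximum-likelihood search for the Weibull lag window of
#' one climate variable.  The objective profiled over window parameters
#' is the AICc of the inner counting-process Cox fit on a reference model
#' containing both climate main effects and their interaction (no age
#' interactions) — the simplest spec adequate for window estimation; the
#' reference terms are configurable.
#'
#' @param variable `"mint"` or `"dtr"`.
#' @param max_lag window length T in days (default 120).
#' @param restarts number of jittered Nelder-Mead restarts (>= 1,
#'   default 8; the profile surface is non-convex).
#' @param bounds named list of `c(lower, upper)` for `shape`, `scale`,
#'   `location`; location upper must stay below `max_lag`.
#' @param include_interaction include the DTR x MinT interaction in the
#'   reference model (default TRUE).
#' @param maxit Nelder-Mead iteration cap per restart.
#' @param seed seed for the restart jitter stream.
#' @return list of class `window_search_config`.
#' @export
window_search_config <- function(variable = c("mint", "dtr"),
                                 max_lag = 120L,
                                 restarts = 8L,
                                 bounds = list(shape = c(0.1, 10),
                                               scale = c(0.2, 300),
                                               location = NULL),
                                 include_interaction = TRUE,
                                 maxit = 250L,
                                 seed = 1L) {
  variable <- match.arg(variable)
  max_lag <- as.integer(max_lag)
  restarts <- as.integer(restarts)
  if (restarts < 1L) stop("'restarts' must be >= 1", call. = FALSE)
  if (is.null(bounds$location)) bounds$location <- c(0, max_lag - 1)
  for (nm in c("shape", "scale")) {
    b <- bounds[[nm]]
    if (length(b) != 2L || b[1L] <= 0 || b[2L] <= b[1L])
      stop(sprintf("bounds for '%s' must be positive and increasing", nm),
           call. = FALSE)
  }
  if (bounds$location[1L] < 0 || bounds$location[2L] >= max_lag)
    stop("location bounds must lie in [0, max_lag)", call. = FALSE)
  structure(list(variable = variable, max_lag = max_lag,
                 restarts = restarts, bounds = bounds,
                 include_interaction = isTRUE(include_interaction),
                 maxit = as.integer(maxit), seed = as.integer(seed)),
            class = "window_search_config")
}

# ---------------------------------------------------------------------------
# Search context: a collapsed counting-process skeleton.
#
# During window search the reference model has no individual-level terms,
# so every covariate is a function of the calendar day only.  Rows that
# share (entry day, study day) are then exchangeable and can be collapsed
# into one case-weighted row; event rows are kept un-collapsed so the
# Efron tie correction sees the true number of deaths.  This reduces an
# 800-individual x 3-year expansion from ~10^6 rows to a few 10^4 and
# makes the repeated inner Cox fits of the profile search cheap, while
# producing exactly the same partial likelihood.
# ---------------------------------------------------------------------------
search_context <- function(events, climate, burn_in = 120L,
                           include_interaction = TRUE) {
  stopifnot(inherits(climate, "daily_climate"))
  n_days <- nrow(climate)
  follow <- events$exit_day - events$entry_day
  keep <- follow > burn_in
  if (!any(keep))
    stop("no individual survives the burn-in", call. = FALSE)
  ev <- events[keep, , drop = FALSE]
  follow <- follow[keep]

  dt <- data.table::data.table(entry = ev$entry_day, follow = follow,
                               event = ev$event)
  # censored-exposure rows: weight = number at risk minus deaths
  agg <- dt[, {
    tmax <- max(follow)
    t <- seq.int(burn_in + 1L, tmax)
    at_risk <- rev(cumsum(rev(tabulate(pmax(follow - burn_in, 0L),
                                       nbins = tmax - burn_in))))
    deaths <- tabulate(follow[event == 1L] - burn_in, nbins = tmax - burn_in)
    list(t = t, w = at_risk - deaths, deaths = deaths)
  }, by = entry]
  cens <- agg[w > 0, .(entry, t, weight = as.numeric(w), event = 0L)]
  dths <- agg[deaths > 0, .(entry = rep(entry, deaths), t = rep(t, deaths),
                            weight = 1, event = 1L)]
  rows <- rbind(cens, dths)
  rows[, `:=`(start = as.numeric(t - 1L), stop = as.numeric(t),
              day = entry + t)]
  if (max(rows$day) > n_days)
    stop("climate record too short for the requested follow-up", call. = FALSE)
  pieces <- engine_pieces(rows)
  n_events <- sum(rows$event)
  if (n_events < 2L) stop("need at least 2 events for the window search",
                          call. = FALSE)
  ctx <- new.env(parent = emptyenv())
  ctx$rows <- rows
  ctx$pieces <- pieces
  ctx$day <- rows$day
  ctx$weight <- rows$weight
  ctx$n_events <- n_events
  ctx$climate <- climate
  ctx$burn_in <- burn_in
  ctx$include_interaction <- include_interaction
  ctx$warm <- NULL
  ctx$failures <- 0L
  ctx$memo_key <- NULL
  ctx$memo_val <- NULL
  ctx
}

# inner Cox AICc for given window(s); variable gets `win`, the other
# variable keeps `other_win`.  The other variable's weighted series is
# fixed over a whole search, so it is memoised on the context.
ctx_objective <- function(ctx, variable, win, other_win) {
  wkey <- function(w) paste(w$shape, w$scale, w$location, w$max_lag,
                            isTRUE(w$flat))
  weighted_series <- function(varname, w) {
    key <- paste(varname, wkey(w))
    if (identical(ctx$memo_key, key)) return(ctx$memo_val)
    val <- build_weighted_covariate(ctx$climate[[varname]], w)
    ctx$memo_key <- key; ctx$memo_val <- val
    val
  }
  other <- setdiff(c("mint", "dtr"), variable)
  wv_day <- build_weighted_covariate(ctx$climate[[variable]], win)
  wo_day <- weighted_series(other, other_win)
  if (variable == "dtr") { wd_day <- wv_day; wm_day <- wo_day
  } else { wd_day <- wo_day; wm_day <- wv_day }
  wd <- wd_day[ctx$day]; wm <- wm_day[ctx$day]
  if (anyNA(wd) || anyNA(wm))
    stop("window burn-in exceeds the excluded prefix; increase burn_in",
         call. = FALSE)
  wsum <- sum(ctx$weight)
  wd <- wd - sum(wd * ctx$weight) / wsum
  wm <- wm - sum(wm * ctx$weight) / wsum
  X <- if (ctx$include_interaction) cbind(wd, wm, wd * wm) else cbind(wd, wm)
  # 1e-6 gradient tolerance: AICc contrasts of interest are O(1), and the
  # looser inner tolerance roughly halves the Newton iterations per
  # candidate window
  fit <- tryCatch(
    cox_newton(X, ctx$pieces, tol = 1e-6, max_iter = 30L,
               init = if (!is.null(ctx$warm) && length(ctx$warm) == ncol(X))
                 ctx$warm else NULL),
    error = function(e) NULL)
  if (is.null(fit)) { ctx$failures <- ctx$failures + 1L; return(list(aicc = 1e10)) }
  ctx$warm <- fit$beta
  list(aicc = aicc(fit$loglik, ncol(X), ctx$n_events),
       loglik = fit$loglik, beta = fit$beta, p = ncol(X))
}

#' Profile objective for a candidate window
#'
#' Builds the lag-weighted covariate for `variable` with the given window
#' parameters, refits the reference Cox model, and returns its AICc — a
#' pure function of its inputs.  The window's own parameters are not
#' added to the inner AICc; comparisons that need them (between-group
#' window tests) add them explicitly.
#'
#' @param params numeric `c(shape, scale, location)`.
#' @param variable `"mint"` or `"dtr"`.
#' @param events a `cohort_events` table.
#' @param climate a `daily_climate`.
#' @param other_window [weibull_window()] used for the other climate
#'   variable (default: flat window of the same length).
#' @param max_lag window length in days.
#' @param burn_in excluded days after entry; defaults to `max_lag` so all
#'   candidate fits share one event set.
#' @return The inner Cox model's AICc.
#' @export
profile_objective <- function(params, variable, events, climate,
                              other_window = NULL, max_lag = 120L,
                              burn_in = max_lag) {
  variable <- match.arg(variable, c("mint", "dtr"))
  if (is.null(other_window)) other_window <- flat_window(max_lag)
  ctx <- search_context(events, climate, burn_in = burn_in)
  win <- weibull_window(params[1L], params[2L], params[3L], max_lag)
  ctx_objective(ctx, variable, win, other_window)$aicc
}

# accept either a weibull_window or a window_search_result
as_window <- function(x) {
  if (inherits(x, "window_search_result")) x$window
  else if (inherits(x, "weibull_window")) x
  else stop("expected a weibull_window or window_search_result", call. = FALSE)
}

# bounded Nelder-Mead via log / logit reparameterisation
to_unconstrained <- function(par, bounds) {
  c(log(par[1L]), log(par[2L]),
    stats::qlogis((par[3L] - bounds$location[1L] + 1e-9) /
                    (diff(bounds$location) + 2e-9)))
}
to_natural <- function(tpar, bounds) {
  clamp <- function(v, b) pmin(pmax(v, b[1L]), b[2L])
  c(clamp(exp(tpar[1L]), bounds$shape),
    clamp(exp(tpar[2L]), bounds$scale),
    bounds$location[1L] +
      stats::plogis(tpar[3L]) * diff(bounds$location))
}

#' Estimate the Weibull lag window of one climate variable
#'
#' Multi-start Nelder-Mead (on log / logit transformed parameters, which
#' enforces the bounds) over (shape, scale, location), minimising the
#' profile AICc of the inner Cox fit.  Deterministic given
#' `config$seed`.  The returned window is the best parameter vector
#' *evaluated* anywhere during the search, so the result can never be
#' worse than an evaluated candidate.
#'
#' @param config a [window_search_config()].
#' @param events a `cohort_events` table.
#' @param climate a `daily_climate`.
#' @param other_window window used to weight the other climate variable
#'   during this search (flat by default; pass the other variable's
#'   current best during sequential estimation).
#' @param burn_in excluded prefix; default `config$max_lag` so all
#'   candidate fits use identical event sets.
#' @return `window_search_result`: `window` (best [weibull_window()]),
#'   `aicc`, `restarts` (per-restart log), `summary` (days to 50/80/100%
#'   cumulative weight), `boundary` flag, `n_inner_failures`.
#' @export
optimize_window <- function(config, events, climate, other_window = NULL,
                            burn_in = config$max_lag) {
  stopifnot(inherits(config, "window_search_config"))
  if (is.null(other_window)) other_window <- flat_window(config$max_lag)
  ctx <- search_context(events, climate, burn_in = burn_in,
                        include_interaction = config$include_interaction)
  T_ <- config$max_lag
  bounds <- config$bounds
  best <- list(val = Inf, par = NULL)
  evalfn <- function(tpar) {
    par <- to_natural(tpar, bounds)
    win <- weibull_window(par[1L], par[2L], par[3L], T_)
    val <- tryCatch(ctx_objective(ctx, config$variable, win, other_window)$aicc,
                    error = function(e) 1e10)
    if (val < best$val) best <<- list(val = val, par = par)
    val
  }
  # deterministic jittered starting grid
  starts <- with_seed(config$seed, "search", {
    base <- rbind(c(1, 0.7, 0), c(1.2, 45, 0), c(0.9, 1.5, 0),
                  c(2.5, 80, 5), c(1.5, 10, 0), c(1.5, 120, 10),
                  c(3, 25, 0), c(1, 60, 30))
    idx <- rep(seq_len(nrow(base)), length.out = config$restarts)
    jit <- matrix(stats::rnorm(config$restarts * 3, 0, 0.15),
                  ncol = 3)
    lapply(seq_len(config$restarts), function(i) {
      p <- base[idx[i], ]
      p <- c(p[1L] * exp(jit[i, 1L]), p[2L] * exp(jit[i, 2L]),
             max(0, p[3L] + 3 * jit[i, 3L]))
      to_natural(to_unconstrained(pmax(p, c(bounds$shape[1L],
                                            bounds$scale[1L], 0)), bounds),
                 bounds)
    })
  })
  restart_log <- data.frame()
  for (i in seq_along(starts)) {
    ctx$warm <- NULL
    t0 <- to_unconstrained(starts[[i]], bounds)
    opt <- stats::optim(t0, evalfn, method = "Nelder-Mead",
                        control = list(maxit = config$maxit,
                                       reltol = 1e-7))
    parn <- to_natural(opt$par, bounds)
    restart_log <- rbind(restart_log, data.frame(
      restart = i, start_shape = starts[[i]][1L],
      start_scale = starts[[i]][2L], start_location = starts[[i]][3L],
      shape = parn[1L], scale = parn[2L], location = parn[3L],
      aicc = opt$value, evaluations = opt$counts[1L],
      converged = opt$convergence == 0))
  }
  win <- weibull_window(best$par[1L], best$par[2L], best$par[3L], T_)
  near <- function(v, b) min(abs(v - b)) < 1e-3
  boundary <- near(best$par[1L], bounds$shape) ||
    near(best$par[2L], bounds$scale) || near(best$par[3L], bounds$location)
  if (boundary)
    warning("window search returned a boundary solution; interpret with care",
            call. = FALSE)
  structure(list(
    window = win, aicc = best$val,
    variable = config$variable,
    restarts = restart_log,
    summary = c(d50 = days_to_fraction(win, 0.5),
                d80 = days_to_fraction(win, 0.8),
                d100 = days_to_fraction(win, 1)),
    boundary = boundary,
    n_inner_failures = ctx$failures,
    burn_in = burn_in),
    class = "window_search_result")
}

#' @export
print.window_search_result <- function(x, ...) {
  cat(sprintf("Window search (%s): profile AICc %.3f%s\n", x$variable,
              x$aicc, if (x$boundary) "  [boundary solution]" else ""))
  print(x$window)
  invisible(x)
}

#' Sequential window estimation for both climate variables
#'
#' Estimates the MinT window first (DTR weighted by a flat window), then
#' the DTR window with the MinT window fixed at its current best, then
#' one refinement pass over MinT.  A joint 6-parameter search is
#' available behind `joint = TRUE`.
#'
#' @param events a `cohort_events` table.
#' @param climate a `daily_climate`.
#' @param max_lag shared window length T.
#' @param restarts,maxit,seed forwarded to [window_search_config()].
#' @param burn_in shared excluded prefix (default `max_lag`).
#' @param joint use a joint 6-parameter Nelder-Mead instead of the
#'   sequential scheme.
#' @return list with elements `mint` and `dtr` (each a
#'   `window_search_result`).
#' @export
estimate_windows <- function(events, climate, max_lag = 120L, restarts = 8L,
                             maxit = 250L, seed = 1L, burn_in = max_lag,
                             joint = FALSE) {
  cfg <- function(v, s) window_search_config(v, max_lag = max_lag,
                                             restarts = restarts,
                                             maxit = maxit, seed = s)
  if (joint) return(estimate_windows_joint(events, climate, max_lag,
                                           restarts, maxit, seed, burn_in))
  res_m <- optimize_window(cfg("mint", seed), events, climate,
                           other_window = flat_window(max_lag),
                           burn_in = burn_in)
  res_d <- optimize_window(cfg("dtr", seed + 1L), events, climate,
                           other_window = res_m$window, burn_in = burn_in)
  res_m <- optimize_window(cfg("mint", seed + 2L), events, climate,
                           other_window = res_d$window, burn_in = burn_in)
  list(mint = res_m, dtr = res_d)
}

# joint 6-parameter search; same transforms, single Nelder-Mead per restart
estimate_windows_joint <- function(events, climate, max_lag, restarts,
                                   maxit, seed, burn_in) {
  ctx <- search_context(events, climate, burn_in = burn_in)
  cfg <- window_search_config("mint", max_lag = max_lag, restarts = restarts,
                              maxit = maxit, seed = seed)
  bounds <- cfg$bounds
  best <- list(val = Inf, par = NULL)
  evalfn <- function(tp) {
    pm <- to_natural(tp[1:3], bounds); pd <- to_natural(tp[4:6], bounds)
    wm <- weibull_window(pm[1L], pm[2L], pm[3L], max_lag)
    wd <- weibull_window(pd[1L], pd[2L], pd[3L], max_lag)
    val <- tryCatch(ctx_objective(ctx, "mint", wm, wd)$aicc,
                    error = function(e) 1e10)
    if (val < best$val) best <<- list(val = val, par = c(pm, pd))
    val
  }
  starts <- with_seed(seed, "search", {
    lapply(seq_len(restarts), function(i)
      c(exp(log(1) + stats::rnorm(1, 0, .3)), exp(log(3) + stats::rnorm(1, 0, .8)), 0,
        exp(log(1.5) + stats::rnorm(1, 0, .3)), exp(log(60) + stats::rnorm(1, 0, .8)), 0))
  })
  for (s in starts) {
    ctx$warm <- NULL
    stats::optim(c(to_unconstrained(s[1:3], bounds),
                   to_unconstrained(s[4:6], bounds)),
                 evalfn, method = "Nelder-Mead",
                 control = list(maxit = maxit * 2L, reltol = 1e-7))
  }
  mk <- function(p, v) {
    win <- weibull_window(p[1L], p[2L], p[3L], max_lag)
    structure(list(window = win, aicc = best$val, variable = v,
                   restarts = data.frame(),
                   summary = c(d50 = days_to_fraction(win, .5),
                               d80 = days_to_fraction(win, .8),
                               d100 = days_to_fraction(win, 1)),
                   boundary = FALSE, n_inner_failures = ctx$failures,
                   burn_in = burn_in),
              class = "window_search_result")
  }
  list(mint = mk(best$par[1:3], "mint"), dtr = mk(best$par[4:6], "dtr"))
}

#' Cross-variable window swap test
#'
#' Weights `variable` by the *other* variable's window and compares the
#' fit against weighting it by its own window (the other variable keeps
#' its own window in both fits).  Positive values favour the own window.
#'
#' @param events,climate data as elsewhere.
#' @param windows named list with [weibull_window()] elements `mint` and
#'   `dtr` (typically from [estimate_windows()]).
#' @param variable which variable gets the foreign window.
#' @param burn_in shared excluded prefix.
#' @return list: `delta_aicc` (= AICc(foreign) - AICc(own)), `aicc_own`,
#'   `aicc_foreign`.
#' @export
swap_window_test <- function(events, climate, windows,
                             variable = c("dtr", "mint"),
                             burn_in = NULL) {
  variable <- match.arg(variable)
  windows <- lapply(windows, as_window)
  if (is.null(burn_in))
    burn_in <- max(windows$mint$max_lag, windows$dtr$max_lag)
  other <- setdiff(c("mint", "dtr"), variable)
  ctx <- search_context(events, climate, burn_in = burn_in)
  own <- ctx_objective(ctx, variable, windows[[variable]], windows[[other]])$aicc
  ctx$warm <- NULL
  foreign <- ctx_objective(ctx, variable, windows[[other]], windows[[other]])$aicc
  list(delta_aicc = foreign - own, aicc_own = own, aicc_foreign = foreign,
       variable = variable)
}

#' Do lag windows differ between treatment groups?
#'
#' Compares stratum-specific windows against one shared window for a
#' climate variable, on AICc with the window parameters counted: the
#' separate-windows model spends 3 extra parameters.  Both alternatives
#' keep stratum-specific Cox coefficients, so the comparison isolates the
#' window shape.  Returns `delta_aicc = AICc(separate) - AICc(shared)`;
#' positive values mean the shared window is preferred.
#'
#' @param events,climate data as elsewhere.
#' @param variable `"mint"` or `"dtr"`.
#' @param by stratifying column of `events` (default `"foraging"`).
#' @param other_window window for the other climate variable (shared
#'   across strata, the usual practice when windows are shared).
#' @param max_lag,restarts,maxit,seed,burn_in search controls.
#' @return list: `delta_aicc`, `preferred` ("shared"/"separate"),
#'   per-stratum and shared `window_search_result`s.
#' @export
compare_windows_between_groups <- function(events, climate,
                                           variable = c("dtr", "mint"),
                                           by = "foraging",
                                           other_window = NULL,
                                           max_lag = 120L, restarts = 4L,
                                           maxit = 250L, seed = 1L,
                                           burn_in = max_lag) {
  variable <- match.arg(variable)
  if (is.null(other_window)) other_window <- flat_window(max_lag)
  levs <- unique(events[[by]])
  if (length(levs) < 2L) stop("need at least two strata", call. = FALSE)
  strata <- lapply(levs, function(l) events[events[[by]] == l, , drop = FALSE])
  for (s in strata)
    if (sum(s$event[s$exit_day - s$entry_day > burn_in]) == 0)
      stop("a stratum has no events after burn-in", call. = FALSE)

  fit_one <- function(ev, sd) {
    cfg <- window_search_config(variable, max_lag = max_lag,
                                restarts = restarts, maxit = maxit,
                                seed = sd)
    optimize_window(cfg, ev, climate, other_window = other_window,
                    burn_in = burn_in)
  }
  sep <- lapply(seq_along(strata), function(i) fit_one(strata[[i]], seed + i))
  # stratum logliks at each stratum's own window
  ll_of <- function(ev, win) {
    ctx <- search_context(ev, climate, burn_in = burn_in)
    o <- ctx_objective(ctx, variable, win, other_window)
    list(loglik = o$loglik, p = o$p, n = ctx$n_events)
  }
  parts_sep <- Map(function(ev, r) ll_of(ev, r$window), strata, sep)
  n_tot <- sum(vapply(parts_sep, `[[`, 0, "n"))
  p_cox <- sum(vapply(parts_sep, `[[`, 0, "p"))
  ll_sep <- sum(vapply(parts_sep, `[[`, 0, "loglik"))
  aicc_sep <- aicc(ll_sep, p_cox + 3L * length(strata), n_tot)

  # shared window: maximise the summed stratum loglik over one window
  ctxs <- lapply(strata, function(ev) search_context(ev, climate,
                                                     burn_in = burn_in))
  cfg <- window_search_config(variable, max_lag = max_lag,
                              restarts = restarts, maxit = maxit,
                              seed = seed)
  bounds <- cfg$bounds
  best <- list(val = Inf, par = NULL, ll = NA)
  evalfn <- function(tp) {
    par <- to_natural(tp, bounds)
    win <- weibull_window(par[1L], par[2L], par[3L], max_lag)
    ll <- tryCatch(sum(vapply(ctxs, function(cx)
      ctx_objective(cx, variable, win, other_window)$loglik, 0)),
      error = function(e) -1e10)
    val <- aicc(ll, p_cox + 3L, n_tot)
    if (val < best$val) best <<- list(val = val, par = par, ll = ll)
    val
  }
  starts <- c(lapply(sep, function(r)
    c(r$window$shape, r$window$scale, r$window$location)),
    list(c(1, 5, 0), c(1.5, 60, 0)))
  for (s in starts[seq_len(min(length(starts), restarts + 2L))])
    stats::optim(to_unconstrained(s, bounds), evalfn,
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-7))
  shared_win <- weibull_window(best$par[1L], best$par[2L], best$par[3L],
                               max_lag)
  delta <- aicc_sep - best$val
  list(delta_aicc = delta,
       preferred = if (delta >= 0) "shared" else "separate",
       shared_window = shared_win, aicc_shared = best$val,
       aicc_separate = aicc_sep,
       separate = stats::setNames(sep, levs))
}
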