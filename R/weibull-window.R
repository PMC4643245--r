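#' Three-parameter Weibull lag-weight window
#'
#' A lag-weight window collapses the last `max_lag` days of a daily climate
#' series into a single covariate.  The raw weight at lag `t` (days before
#' the event day, `t = 1` being the preceding day) is the three-parameter
#' Weibull density
#' \deqn{w(t) = (k/\lambda)\,((t-\theta)/\lambda)^{k-1}
#'              \exp\{-((t-\theta)/\lambda)^k\}, \quad t > \theta,}
#' with shape \eqn{k}, scale \eqn{\lambda} (days) and location \eqn{\theta}
#' (days); `w(t) = 0` for `t <= location` when `shape > 1` (and at
#' `t < location` generally).  The density is evaluated at the integer lags
#' `1..max_lag` and renormalised to sum to one, matching the daily
#' partition of the survival data.
#'
#' @param shape positive shape parameter (dimensionless).
#' @param scale positive scale parameter (days).
#' @param location non-negative location (onset delay, days).
#' @param max_lag window length `T` in days; weights cover lags `1..T`.
#' @return An object of class `weibull_window`.
#' @examples
#' w <- weibull_window(shape = 1.5, scale = 65, max_lag = 120)
#' sum(normalized_weights(w))    # 1
#' days_to_fraction(w, 0.8)      # lag containing 80% of cumulative weight
#' @export
weibull_window <- function(shape, scale, location = 0, max_lag = 120L) {
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) || shape <= 0)
    stop("'shape' must be a single positive number", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("'scale' must be a single positive number", call. = FALSE)
  if (!is.numeric(location) || length(location) != 1L || !is.finite(location) || location < 0)
    stop("'location' must be a single non-negative number", call. = FALSE)
  max_lag <- as.integer(max_lag)
  if (is.na(max_lag) || max_lag < 1L)
    stop("'max_lag' must be an integer >= 1", call. = FALSE)
  structure(
    list(shape = as.numeric(shape), scale = as.numeric(scale),
         location = as.numeric(location), max_lag = max_lag),
    class = "weibull_window"
  )
}

#' @export
print.weibull_window <- function(x, ...) {
  cat(sprintf("Weibull lag window: shape = %.4g, scale = %.4g d, location = %.4g d, T = %d d\n",
              x$shape, x$scale, x$location, x$max_lag))
  q <- vapply(c(0.5, 0.8, 1), function(f) days_to_fraction(x, f), numeric(1))
  cat(sprintf("  cumulative weight reaches 50%% / 80%% / 100%% at lag %d / %d / %d days\n",
              q[1L], q[2L], q[3L]))
  invisible(x)
}

#' Raw Weibull lag weight
#'
#' Evaluates the (unnormalised) three-parameter Weibull density at integer
#' or real lags.  Returns 0 for lags before the location parameter.
#'
#' @param lag lag in days (vectorised), `lag >= 1`.
#' @param window a [weibull_window()].
#' @return Numeric vector of raw (unnormalised) weights.
#' @export
weibull_weight <- function(lag, window) {
  stopifnot(inherits(window, "weibull_window"))
  if (any(lag < 1)) stop("'lag' must be >= 1", call. = FALSE)
  k <- window$shape; lam <- window$scale; theta <- window$location
  z <- (lag - theta) / lam
  w <- numeric(length(lag))
  pos <- z > 0
  w[pos] <- (k / lam) * z[pos]^(k - 1) * exp(-z[pos]^k)
  # at z == 0 the density is 0 for k > 1, k/lambda for k == 1, +Inf for k < 1;
  # treat the boundary as 0 so weights stay finite
  w[!is.finite(w)] <- 0
  w
}

#' Normalised lag weights over the window
#'
#' @param window a [weibull_window()].
#' @return Numeric vector of length `max_lag` summing to 1.
#' @export
normalized_weights <- function(window) {
  stopifnot(inherits(window, "weibull_window"))
  w <- weibull_weight(seq_len(window$max_lag), window)
  s <- sum(w)
  if (!is.finite(s) || s <= 0)
    stop("degenerate window: all raw weights are zero over lags 1..",
         window$max_lag, call. = FALSE)
  w / s
}

#' Cumulative weight curve
#'
#' @param window a [weibull_window()].
#' @return data.frame with columns `lag`, `weight`, `cumulative`.
#' @export
cumulative_weight <- function(window) {
  w <- normalized_weights(window)
  data.frame(lag = seq_along(w), weight = w, cumulative = cumsum(w))
}

#' Days needed to accumulate a fraction of the window weight
#'
#' Returns the smallest lag whose cumulative normalised weight reaches `q`;
#' the field's usual summary of a lag window ("80% of the effect within
#' so-many days").
#'
#' @param window a [weibull_window()].
#' @param q fraction in (0, 1].
#' @return Integer lag in days.
#' @export
days_to_fraction <- function(window, q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q > 1)
    stop("'q' must be a single number in (0, 1]", call. = FALSE)
  cw <- cumsum(normalized_weights(window))
  # guard against accumulated rounding at q = 1
  idx <- which(cw >= q - 1e-12)
  if (!length(idx)) window$max_lag else as.integer(idx[1L])
}

#' Flat (uniform) lag window
#'
#' Equal weight `1/T` on every lag; the reference window used in null
#' comparisons against the fitted Weibull window.
#'
#' @param max_lag window length in days.
#' @return An object of class `weibull_window` flagged as flat.
#' @export
flat_window <- function(max_lag = 120L) {
  # shape 1 with a huge scale is numerically uniform, but carry an exact
  # flat flag so tests are not at the mercy of exp() rounding
  w <- weibull_window(shape = 1, scale = 1e12, location = 0, max_lag = max_lag)
  w$flat <- TRUE
  class(w) <- c("flat_window", class(w))
  w
}

#' Build a weighted climate covariate
#'
#' Collapses a daily series `x` into the lag-weighted covariate
#' \eqn{X_w(d) = \sum_{t=1}^{T} w(t)\, x(d - t)}.  The value at day `d`
#' uses only strictly preceding days; days with fewer than `T` days of
#' history are `NA` (the burn-in).
#'
#' @param x numeric daily series, or a `daily_climate` object together
#'   with `variable`.
#' @param window a [weibull_window()].
#' @param variable which column to weight when `x` is a `daily_climate`
#'   ("mint", "dtr" or "maxt").
#' @param center if `TRUE`, subtract `center_value` (or the mean over
#'   defined days when `center_value` is `NULL`) and record the constant.
#' @param center_value optional explicit centering constant; the analysis
#'   layer passes the mean over included bird-days here.
#' @return Numeric vector of length `length(x)` with attributes
#'   `window`, `variable`, `center` (the constant, 0 if uncentered).
#'   First `max_lag` entries are `NA`.
#' @export
build_weighted_covariate <- function(x, window, variable = NULL,
                                     center = FALSE, center_value = NULL) {
  if (inherits(x, "daily_climate")) {
    if (is.null(variable))
      stop("supply 'variable' (mint, dtr or maxt) for a daily_climate input",
           call. = FALSE)
    variable <- match.arg(tolower(variable), c("mint", "dtr", "maxt"))
    x <- x[[variable]]
  }
  stopifnot(inherits(window, "weibull_window"), is.numeric(x))
  T_ <- window$max_lag
  if (length(x) <= T_)
    stop(sprintf("burn-in not satisfied: need > %d days of history, got %d; first valid day would be %d",
                 T_, length(x), T_ + 1L), call. = FALSE)
  w <- if (isTRUE(window$flat)) rep(1 / T_, T_) else normalized_weights(window)
  n <- length(x)
  # X_w(d) = sum_t w(t) x(d - t): a one-sided convolution
  out <- rep(NA_real_, n)
  idx <- (T_ + 1L):n
  acc <- numeric(length(idx))
  for (t in seq_len(T_)) acc <- acc + w[t] * x[idx - t]
  out[idx] <- acc
  ctr <- 0
  if (isTRUE(center)) {
    ctr <- if (is.null(center_value)) mean(out[idx]) else center_value
    out[idx] <- out[idx] - ctr
  }
  attr(out, "window") <- window
  attr(out, "variable") <- variable
  attr(out, "center") <- ctr
  out
}

#' Write a weighted series to CSV
#'
#' Header comment lines record the variable and window parameters, then a
#' regular `date,value` table follows.
#'
#' @param x a weighted covariate from [build_weighted_covariate()].
#' @param dates vector of dates matching `x`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_weighted_series <- function(x, dates, path) {
  w <- attr(x, "window")
  hdr <- c(
    sprintf("# variable: %s", attr(x, "variable") %||% "unknown"),
    sprintf("# window: shape=%.10g scale=%.10g location=%.10g max_lag=%d",
            w$shape, w$scale, w$location, w$max_lag),
    sprintf("# center: %.10g", attr(x, "center") %||% 0)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(date = dates, value = as.numeric(x)),
                   con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
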