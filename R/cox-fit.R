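#' Counting-process Cox partial log likelihood
#'
#' Evaluates the Efron-corrected partial log likelihood at a given
#' coefficient vector, with the risk set at an event time `t` defined as
#' all rows with `start < t <= stop`.
#'
#' @param beta coefficient vector (length = number of terms).
#' @param data a `cohort_intervals` table.
#' @param spec a [cox_model_spec()]; its terms define the design columns.
#' @return The partial log likelihood (a scalar).
#' @export
partial_loglik <- function(beta, data, spec) {
  X <- spec_design(data, spec)
  if (length(beta) != ncol(X))
    stop("length(beta) must equal the number of terms", call. = FALSE)
  if (any(!is.finite(beta))) stop("'beta' must be finite", call. = FALSE)
  pieces <- engine_pieces(data)
  res <- cox_engine_cpp(X, pieces$start, pieces$stop, pieces$event,
                        pieces$weight, as.numeric(beta),
                        pieces$ord_add, pieces$ord_rem, pieces$death_ord, 0L)
  res$loglik
}

# shared preparation for the C++ engine: 0-based orderings
engine_pieces <- function(data) {
  start <- as.numeric(data$start)
  stop_ <- as.numeric(data$stop)
  event <- as.integer(data$event)
  weight <- if ("weight" %in% names(data)) as.numeric(data$weight)
            else rep(1, nrow(data))
  if (any(start >= stop_))
    stop("interval rows must satisfy start < stop", call. = FALSE)
  list(start = start, stop = stop_, event = event, weight = weight,
       ord_add = order(stop_, decreasing = TRUE) - 1L,
       ord_rem = order(start, decreasing = TRUE) - 1L,
       death_ord = {
         w <- which(event == 1L)
         w[order(stop_[w], decreasing = TRUE)] - 1L
       })
}

# Newton-Raphson with step halving on a prepared design matrix.  The
# Newton step is capped at infinity-norm 10 per iteration: profile
# searches visit degenerate candidate windows whose near-collinear
# designs make the information matrix ill-conditioned, and an uncapped
# solve can then propose steps that overflow exp().
cox_newton <- function(X, pieces, init = NULL, tol = 1e-8, max_iter = 50L) {
  p <- ncol(X)
  if (!length(pieces$death_ord))
    stop("no events in the data; the partial likelihood is undefined",
         call. = FALSE)
  beta <- if (is.null(init)) numeric(p) else as.numeric(init)
  trace <- matrix(NA_real_, max_iter, 2L,
                  dimnames = list(NULL, c("loglik", "max_grad")))
  res <- cox_engine_cpp(X, pieces$start, pieces$stop, pieces$event,
                        pieces$weight, beta, pieces$ord_add, pieces$ord_rem,
                        pieces$death_ord, 1L)
  if (p == 0L)
    return(list(beta = beta, loglik = res$loglik, info = res$info,
                n_events = res$n_events, iter = 0L, converged = TRUE,
                trace = trace[0, , drop = FALSE]))
  for (it in seq_len(max_iter)) {
    trace[it, ] <- c(res$loglik, max(abs(res$grad)))
    if (max(abs(res$grad)) < tol)
      return(list(beta = beta, loglik = res$loglik, info = res$info,
                  grad = res$grad, n_events = res$n_events,
                  iter = it - 1L, converged = TRUE,
                  trace = trace[seq_len(it), , drop = FALSE]))
    step <- tryCatch(solve(res$info, res$grad), error = function(e) NULL)
    if (is.null(step)) {
      ev <- eigen(res$info, symmetric = TRUE, only.values = TRUE)$values
      stop(sprintf("information matrix is singular (min eigenvalue %.3g); aliased or collinear terms",
                   min(ev)), call. = FALSE)
    }
    m <- max(abs(step))
    if (m > 10) step <- step * (10 / m)
    # step halving: insist the likelihood does not decrease (tolerance well
    # below any AICc contrast of interest, but above float noise on the
    # O(10^3) logliks of daily interval data)
    ok <- FALSE
    for (h in 0:15) {
      cand <- beta + step / 2^h
      res_new <- cox_engine_cpp(X, pieces$start, pieces$stop, pieces$event,
                                pieces$weight, cand, pieces$ord_add,
                                pieces$ord_rem, pieces$death_ord, 1L)
      if (is.finite(res_new$loglik) && res_new$loglik >= res$loglik - 1e-9) {
        beta <- cand; res <- res_new; ok <- TRUE; break
      }
    }
    if (!ok) {
      # stalled: near-collinear designs can exhaust float precision before
      # the gradient test fires; accept if effectively at the optimum
      if (max(abs(res$grad)) < 1e-2 * max(1, abs(res$loglik) / 1e3))
        return(list(beta = beta, loglik = res$loglik, info = res$info,
                    grad = res$grad, n_events = res$n_events,
                    iter = it, converged = FALSE,
                    trace = trace[seq_len(it), , drop = FALSE]))
      stop("step halving failed to improve the partial likelihood",
           call. = FALSE)
    }
  }
  stop(paste0("Cox fit did not converge in ", max_iter,
              " iterations; trace:\n",
              paste(utils::capture.output(print(round(trace, 6))),
                    collapse = "\n")),
       call. = FALSE)
}

#' Fit a counting-process Cox model
#'
#' Newton-Raphson maximisation of the Efron-corrected partial likelihood
#' (gradient tolerance `1e-8`, step halving, at most 50 iterations) with a
#' cluster-robust (sandwich) variance over the cluster column — the
#' default stand-in for an aviary random effect, preserving the point
#' estimates while acknowledging within-aviary correlation.
#'
#' @param data a `cohort_intervals` table from [expand_to_intervals()].
#' @param spec a [cox_model_spec()].
#' @param init optional starting coefficients.
#' @param tol gradient convergence tolerance.
#' @return An object of class `climsurv_cox`: coefficients, hazard ratios,
#'   model-based and robust standard errors, log partial likelihood (and
#'   its null value), number of events, AICc, convergence metadata, the
#'   centering constants inherited from `data`.
#' @export
fit_cox <- function(data, spec, init = NULL, tol = 1e-8) {
  stopifnot(inherits(spec, "cox_model_spec"))
  X <- spec_design(data, spec)
  if (ncol(X) > 0L) {
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      aliased <- colnames(X)[qrx$pivot[seq.int(qrx$rank + 1L, ncol(X))]]
      stop("design matrix is rank deficient; aliased term(s): ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
  }
  pieces <- engine_pieces(data)
  nr <- cox_newton(X, pieces, init = init, tol = tol)
  if (!nr$converged)
    warning("Cox fit stalled at gradient ", format(max(abs(nr$grad))),
            "; estimates usable but near-collinear terms suspected",
            call. = FALSE)
  p <- ncol(X)

  loglik0 <- if (p == 0L) nr$loglik else {
    cox_engine_cpp(X, pieces$start, pieces$stop, pieces$event, pieces$weight,
                   numeric(p), pieces$ord_add, pieces$ord_rem,
                   pieces$death_ord, 0L)$loglik
  }

  var_model <- if (p > 0L) solve(nr$info) else matrix(0, 0, 0)
  var_robust <- var_model
  if (p > 0L) {
    resid <- cox_engine_cpp(X, pieces$start, pieces$stop, pieces$event,
                            pieces$weight, nr$beta, pieces$ord_add,
                            pieces$ord_rem, pieces$death_ord, 2L)$resid
    cl <- if ("cluster" %in% names(data)) data$cluster else data$id
    U <- rowsum(resid, group = cl)
    var_robust <- var_model %*% crossprod(U) %*% var_model
  }

  n_aicc <- switch(spec$aicc_n,
                   events = nr$n_events,
                   rows = nrow(data),
                   individuals = attr(data, "n_individuals") %||%
                     length(unique(data$id)))
  beta <- stats::setNames(nr$beta, colnames(X))
  # AICc is undefined on tiny data (n <= p + 1); record NA rather than fail
  aicc_val <- if (n_aicc > p + 1) aicc(nr$loglik, p, n_aicc) else NA_real_
  fit <- structure(list(
    coefficients = beta,
    hazard_ratios = exp(beta),
    se = if (p) stats::setNames(sqrt(diag(var_model)), colnames(X))
         else numeric(0),
    robust_se = if (p) stats::setNames(sqrt(diag(var_robust)), colnames(X))
                else numeric(0),
    var = var_model, robust_var = var_robust,
    loglik = nr$loglik, loglik_null = loglik0,
    n_events = nr$n_events, n_rows = nrow(data),
    df = p, aicc = aicc_val,
    aicc_n = n_aicc,
    iter = nr$iter, converged = nr$converged,
    spec = spec,
    centers = attr(data, "centers") %||% c(dtr = 0, mint = 0)),
    class = "climsurv_cox")
  fit
}

#' @export
print.climsurv_cox <- function(x, ...) {
  cat(sprintf("Counting-process Cox fit: %d terms, %g events, loglik %.3f, AICc %.2f\n",
              x$df, x$n_events, x$loglik, x$aicc))
  if (x$df > 0) {
    tab <- data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                      se = x$se, robust_se = x$robust_se)
    print(round(tab, 4))
  }
  invisible(x)
}

#' @export
summary.climsurv_cox <- function(object, ...) {
  z <- object$coefficients / object$robust_se
  tab <- data.frame(coef = object$coefficients,
                    HR = object$hazard_ratios,
                    se = object$se, robust_se = object$robust_se,
                    z = z, p = 2 * stats::pnorm(-abs(z)))
  out <- list(table = tab, loglik = object$loglik, aicc = object$aicc,
              n_events = object$n_events)
  class(out) <- "summary.climsurv_cox"
  out
}

#' @export
print.summary.climsurv_cox <- function(x, ...) {
  print(round(x$table, 5))
  cat(sprintf("loglik %.4f, AICc %.3f, events %g\n",
              x$loglik, x$aicc, x$n_events))
  invisible(x)
}

#' Export a Cox fit as CSV (coefficient table) and JSON (fit record)
#'
#' The CSV carries one row per term: `term`, `coefficient`,
#' `hazard_ratio`, `se`, `robust_se`.  The JSON records `loglik`, `p`
#' (term count), `n_events`, `AICc` and convergence metadata.
#'
#' @param fit a `climsurv_cox`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, a list with the written paths.
#' @export
write_fit_summary <- function(fit, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(fit, "climsurv_cox"))
  if (!is.null(csv_path))
    utils::write.csv(data.frame(term = names(fit$coefficients),
                                coefficient = unname(fit$coefficients),
                                hazard_ratio = unname(fit$hazard_ratios),
                                se = unname(fit$se),
                                robust_se = unname(fit$robust_se)),
                     csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(loglik = fit$loglik,
                              loglik_null = fit$loglik_null,
                              p = fit$df, n_events = fit$n_events,
                              n_rows = fit$n_rows, aicc = fit$aicc,
                              iterations = fit$iter,
                              converged = fit$converged,
                              centers = as.list(fit$centers)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = csv_path, json = json_path))
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 loglik + 2p + 2p(p+1)/(n - p - 1)`.
#'
#' @param loglik maximised log (partial) likelihood.
#' @param p number of estimated parameters.
#' @param n sample size used for the correction (for Cox models the
#'   conventional choice is the number of events).
#' @return The AICc value.
#' @export
aicc <- function(loglik, p, n) {
  if (n <= p + 1)
    stop(sprintf("AICc correction undefined: need n > p + 1 (n = %g, p = %g)",
                 n, p), call. = FALSE)
  -2 * loglik + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Likelihood-ratio test between nested Cox fits
#'
#' @param full,reduced `climsurv_cox` fits of nested specs on the same
#'   data (the reduced model's terms must be a subset of the full's).
#' @return list with `statistic` (X squared), `df`, `p.value`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "climsurv_cox"), inherits(reduced, "climsurv_cox"))
  if (!all(reduced$spec$terms %in% full$spec$terms))
    stop("models are not nested: reduced terms must be a subset of full terms",
         call. = FALSE)
  if (!isTRUE(all.equal(full$n_events, reduced$n_events)) ||
      full$n_rows != reduced$n_rows)
    stop("models were fitted on different data", call. = FALSE)
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- full$df - reduced$df
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else 1
  list(statistic = stat, df = df, p.value = p)
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  if (!length(aicc_values)) stop("empty AICc list", call. = FALSE)
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}
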