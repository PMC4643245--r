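#' Enumerate submodels of a global hazard model
#'
#' All subsets of the global term set that respect marginality
#' (an interaction requires its parent main effects; age interactions
#' require only the non-age parent because current age is absorbed into
#' the baseline hazard), including the baseline-only model.
#'
#' @param global a [cox_model_spec()].
#' @return list of `cox_model_spec` objects, no duplicates.
#' @export
enumerate_submodels <- function(global) {
  stopifnot(inherits(global, "cox_model_spec"))
  terms <- global$terms
  k <- length(terms)
  if (k > 16L)
    stop("refusing to enumerate 2^", k, " submodels; trim the global model",
         call. = FALSE)
  out <- list()
  for (m in 0:(2^k - 1)) {
    sel <- terms[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
    if (length(check_marginality(sel))) next
    out[[length(out) + 1L]] <- cox_model_spec(
      sel, timescale = global$timescale, cluster = global$cluster,
      aicc_n = global$aicc_n)
  }
  out
}

#' All-subsets AICc model selection
#'
#' Fits every marginality-respecting submodel of the global model on the
#' same interval data (hence identical burn-in, centering and event set)
#' and assembles the ranked selection table: per-term hazard ratios, df,
#' AICc, delta AICc and Akaike weights computed over all successfully
#' fitted models.  Non-convergent submodels are recorded with `NA` fit
#' statistics, excluded from the weight normalisation, and flagged with a
#' warning.
#'
#' @param data a `cohort_intervals` table.
#' @param global a [cox_model_spec()].
#' @return A `data.frame` of class `hazard_selection`, sorted by AICc:
#'   one hazard-ratio column per global term (NA when absent), then
#'   `df`, `loglik`, `AICc`, `delta_aicc`, `weight`.  The fitted models
#'   are attached as attribute `fits` (in table order) and the global
#'   spec as `global`.
#' @export
dredge <- function(data, global) {
  specs <- enumerate_submodels(global)
  fits <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    fits[[i]] <- tryCatch(fit_cox(data, specs[[i]]),
                          error = function(e) structure(
                            list(message = conditionMessage(e)),
                            class = "climsurv_cox_failure"))
  }
  failed <- vapply(fits, inherits, TRUE, "climsurv_cox_failure")
  if (any(failed))
    warning(sum(failed), " submodel(s) failed to converge and were ",
            "excluded from the Akaike weights", call. = FALSE)
  aiccs <- ifelse(failed, NA_real_,
                  vapply(fits, function(f) if (inherits(f, "climsurv_cox"))
                    f$aicc else NA_real_, 0))
  w <- rep(NA_real_, length(specs))
  w[!failed] <- akaike_weights(aiccs[!failed])
  hr <- matrix(NA_real_, length(specs), length(global$terms),
               dimnames = list(NULL, global$terms))
  df <- integer(length(specs)); ll <- rep(NA_real_, length(specs))
  for (i in seq_along(specs)) {
    df[i] <- length(specs[[i]]$terms)
    if (!failed[i]) {
      ll[i] <- fits[[i]]$loglik
      hr[i, specs[[i]]$terms] <- fits[[i]]$hazard_ratios
    }
  }
  tab <- data.frame(model = seq_along(specs), hr, df = df, loglik = ll,
                    AICc = aiccs, check.names = FALSE)
  ord <- order(aiccs)   # NAs (failures) sort last
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aicc <- tab$AICc - min(tab$AICc, na.rm = TRUE)
  tab$weight <- w[ord]
  rownames(tab) <- NULL
  tab$model <- seq_len(nrow(tab))
  structure(tab, class = c("hazard_selection", "data.frame"),
            fits = fits[ord], specs = specs[ord], global = global)
}

#' Restrict a selection table to models near the best
#'
#' @param table a `hazard_selection` from [dredge()].
#' @param delta AICc radius (the conventional presentation uses 4).
#' @return The rows with `delta_aicc <= delta`, order preserved, class
#'   and attributes retained.
#' @export
within_delta <- function(table, delta = 4) {
  stopifnot(inherits(table, "hazard_selection"), nrow(table) >= 1L)
  keep <- !is.na(table$delta_aicc) & table$delta_aicc <= delta
  out <- table[keep, , drop = FALSE]
  structure(out, class = class(table),
            fits = attr(table, "fits")[keep],
            specs = attr(table, "specs")[keep],
            global = attr(table, "global"))
}

#' Term support across a selection table
#'
#' How often (and with how much Akaike weight) a term appears among the
#' models of a selection table — typically applied to the models within
#' 4 AICc of the best.
#'
#' @param table a `hazard_selection`.
#' @param term a term label of the global model.
#' @param delta optional AICc radius applied first.
#' @return list: `n_models`, `n_with_term`, `fraction`, `summed_weight`.
#' @export
term_support <- function(table, term, delta = NULL) {
  stopifnot(inherits(table, "hazard_selection"), nrow(table) >= 1L)
  if (!term %in% attr(table, "global")$terms)
    stop("unknown term: ", term, call. = FALSE)
  if (!is.null(delta)) table <- within_delta(table, delta)
  has <- !is.na(table[[term]])
  list(n_models = nrow(table), n_with_term = sum(has),
       fraction = mean(has),
       summed_weight = sum(table$weight[has], na.rm = TRUE))
}

#' @export
print.hazard_selection <- function(x, ...) {
  cat(sprintf("AICc model selection: %d models (global: %s)\n", nrow(x),
              paste(attr(x, "global")$terms, collapse = " + ")))
  print.data.frame(cbind(round(as.data.frame(x)[
    setdiff(names(x), c("loglik"))], 3)), ...)
  invisible(x)
}

#' Export a selection table in the conventional layout
#'
#' One column per candidate term holding the hazard ratio (or NA), then
#' `df`, `AICc`, `delta_aicc`, `weight`.
#'
#' @param table a `hazard_selection`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(table, path) {
  stopifnot(inherits(table, "hazard_selection"))
  cols <- c("model", attr(table, "global")$terms, "df", "AICc",
            "delta_aicc", "weight")
  utils::write.csv(as.data.frame(table)[, cols], path, row.names = FALSE,
                   na = "NA")
  invisible(path)
}
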