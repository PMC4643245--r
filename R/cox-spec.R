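#' Hazard model specification
#'
#' A term list over weighted climate covariates, age-at-entry, sqrt(age)
#' interactions and the developmental treatment, plus the bookkeeping the
#' counting-process fit needs (timescale, cluster term, AICc sample-size
#' convention).
#'
#' Recognised terms: `DTR`, `MinT`, `DTR:MinT`, `AgeStart`,
#' `AgeStart:Age`, `DTR:Age`, `MinT:Age`, `Brood`, `Brood:DTR`,
#' `Brood:Age`, `Photoperiod`, `Sex`.  Current age has no main-effect
#' term: with time-in-study (or age) as the baseline timescale it is
#' absorbed into the baseline hazard, so `Age` may appear only inside
#' interactions, and marginality requires only the non-age parent of an
#' age interaction.  Age is square-root transformed wherever it enters an
#' interaction.
#'
#' @param terms character vector of term labels.
#' @param timescale baseline timescale: `"study"` (time since entry, with
#'   `AgeStart` available as a covariate) or `"age"` (age as time axis
#'   with delayed entry).
#' @param cluster name of the cluster column for the robust variance
#'   (default `"aviary"`).
#' @param aicc_n which sample size enters the AICc small-sample
#'   correction: `"events"` (default, the usual Cox convention),
#'   `"rows"`, or `"individuals"`.
#' @return An object of class `cox_model_spec`.
#' @export
cox_model_spec <- function(terms,
                           timescale = c("study", "age"),
                           cluster = "aviary",
                           aicc_n = c("events", "rows", "individuals")) {
  timescale <- match.arg(timescale)
  aicc_n <- match.arg(aicc_n)
  terms <- unique(as.character(terms))
  known <- names(term_builders())
  bad <- setdiff(terms, known)
  if (length(bad))
    stop("unknown model term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  miss <- check_marginality(terms)
  if (length(miss))
    stop("marginality violated: ", paste(miss, collapse = "; "),
         call. = FALSE)
  structure(list(terms = terms, timescale = timescale, cluster = cluster,
                 aicc_n = aicc_n),
            class = "cox_model_spec")
}

#' @export
print.cox_model_spec <- function(x, ...) {
  cat("Cox model spec (", x$timescale, " timescale, cluster = ", x$cluster,
      ")\n  terms: ",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "(baseline only)",
      "\n", sep = "")
  invisible(x)
}

# parents required for each interaction term; age needs no main effect
# because it is part of the baseline hazard
term_parents <- function(term) {
  if (!grepl(":", term, fixed = TRUE)) return(character(0))
  setdiff(strsplit(term, ":", fixed = TRUE)[[1L]], "Age")
}

check_marginality <- function(terms) {
  msgs <- character(0)
  for (tm in terms) {
    need <- setdiff(term_parents(tm), terms)
    if (length(need))
      msgs <- c(msgs, sprintf("'%s' requires parent term(s) %s", tm,
                              paste(need, collapse = ", ")))
  }
  msgs
}

# each builder maps the per-row covariate table to one design column
term_builders <- function() {
  list(
    "DTR"          = function(d) d$wdtr,
    "MinT"         = function(d) d$wmint,
    "DTR:MinT"     = function(d) d$wdtr * d$wmint,
    "AgeStart"     = function(d) d$agestart,
    "AgeStart:Age" = function(d) d$agestart * d$sqrtage,
    "DTR:Age"      = function(d) d$wdtr * d$sqrtage,
    "MinT:Age"     = function(d) d$wmint * d$sqrtage,
    "Brood"        = function(d) d$brood,
    "Brood:DTR"    = function(d) d$brood * d$wdtr,
    "Brood:Age"    = function(d) d$brood * d$sqrtage,
    "Photoperiod"  = function(d) d$photoperiod,
    "Sex"          = function(d) d$sex_num
  )
}

# design matrix for a spec over a cohort_intervals table
spec_design <- function(data, spec) {
  bld <- term_builders()
  p <- length(spec$terms)
  X <- matrix(0, nrow(data), p,
              dimnames = list(NULL, spec$terms))
  for (j in seq_len(p)) {
    col <- bld[[spec$terms[j]]](data)
    if (is.null(col) || anyNA(col))
      stop(sprintf("covariate for term '%s' is missing or has gaps",
                   spec$terms[j]), call. = FALSE)
    X[, j] <- col
  }
  X
}
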