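#' Multiple linear regression on culture inputs
#'
#' Ordinary least squares of one response on the culture inputs, with
#' intercept. Standard errors come from the unbiased residual variance and
#' the inverse normal-equations matrix; two-sided p-values use the t
#' distribution with `n - k` degrees of freedom. The fit is delegated to
#' [stats::lm()]; `backward_eliminate()` adds iterative removal of
#' non-significant terms.
#'
#' @param x data frame or matrix of predictor columns.
#' @param y numeric response vector.
#' @return object of class `elicit_mlr`: list with `terms` (term names,
#'   intercept first), `coefficients`, `standard_errors`, `t_values`,
#'   `p_values`, `removed` (elimination log, outermost removal first),
#'   `alpha`, and the underlying `lm` fit.
#' @examples
#' d <- simulate_experiment(params = surface_params(seed = 1))
#' fit <- fit_mlr(d[c("ce_conc", "cf_conc", "adding_day", "harvest_day")], d$total)
#' coef(fit)
#' @export
fit_mlr <- function(x, y) {
  x <- as.data.frame(x)
  if (anyNA(x) || anyNA(y)) stopf("NA values in regression inputs")
  if (nrow(x) != length(y)) stopf("nrow(x) != length(y)")
  if (nrow(x) <= ncol(x) + 1L)
    stopf("need n > number of terms (%d rows, %d predictors)",
          nrow(x), ncol(x))
  fit_mlr_terms(x, y, names(x), alpha = NA_real_, removed = character())
}

# Shared worker: OLS on the named subset of columns with singularity check.
fit_mlr_terms <- function(x, y, terms, alpha, removed) {
  dat <- x[terms]
  dat$.response <- y
  lmfit <- stats::lm(.response ~ ., data = dat)
  cf <- stats::coef(lmfit)
  if (anyNA(cf))
    stopf("singular design: collinear column(s): %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(lmfit)$coefficients
  nm <- rownames(sm)
  nm[nm == "(Intercept)"] <- "intercept"
  structure(list(
    terms = nm,
    coefficients = stats::setNames(sm[, "Estimate"], nm),
    standard_errors = stats::setNames(sm[, "Std. Error"], nm),
    t_values = stats::setNames(sm[, "t value"], nm),
    p_values = stats::setNames(sm[, "Pr(>|t|)"], nm),
    removed = removed, alpha = alpha, lm = lmfit,
    predictors = terms
  ), class = "elicit_mlr")
}

#' Backward elimination of non-significant predictors
#'
#' Refits after removing, one per iteration, the non-intercept term with the
#' largest p-value exceeding `alpha`, until every retained term is
#' significant. The intercept is always retained. Idempotent: rerunning on
#' the retained predictors changes nothing.
#'
#' @inheritParams fit_mlr
#' @param alpha significance level for retaining a predictor.
#' @return an `elicit_mlr` fit of the retained terms; `$removed` records the
#'   elimination order.
#' @export
backward_eliminate <- function(x, y, alpha = 0.05) {
  check_number(alpha, "alpha", lower = 0, upper = 1)
  x <- as.data.frame(x)
  keep <- names(x)
  removed <- character()
  repeat {
    fit <- fit_mlr_terms(x, y, keep, alpha, removed)
    p <- fit$p_values[setdiff(fit$terms, "intercept")]
    if (!length(p) || max(p) <= alpha) return(fit)
    worst <- names(p)[which.max(p)]
    removed <- c(removed, worst)
    keep <- setdiff(keep, worst)
    fit$removed <- removed
    if (!length(keep)) {
      # all predictors eliminated: return the intercept-only model
      dat <- data.frame(.response = y)
      lmfit <- stats::lm(.response ~ 1, data = dat)
      sm <- summary(lmfit)$coefficients
      return(structure(list(
        terms = "intercept",
        coefficients = c(intercept = sm[1, 1]),
        standard_errors = c(intercept = sm[1, 2]),
        t_values = c(intercept = sm[1, 3]),
        p_values = c(intercept = sm[1, 4]),
        removed = removed, alpha = alpha, lm = lmfit,
        predictors = character()
      ), class = "elicit_mlr"))
    }
  }
}

#' Rank regression terms by absolute t value
#'
#' A larger |t| marks a more influential model component; ties keep the
#' original column order.
#'
#' @param fit an `elicit_mlr` fit.
#' @return character vector of non-intercept term names, most important first.
#' @export
rank_terms_by_t <- function(fit) {
  stopifnot(inherits(fit, "elicit_mlr"))
  tv <- fit$t_values[setdiff(fit$terms, "intercept")]
  names(tv)[order(-abs(tv))]  # order() is stable: ties keep input order
}

#' t statistic of a regression coefficient
#'
#' @param coefficient,standard_error numeric vectors.
#' @return `coefficient / standard_error`.
#' @export
t_statistic <- function(coefficient, standard_error) {
  if (any(standard_error <= 0)) stopf("standard errors must be positive")
  coefficient / standard_error
}

#' @export
coef.elicit_mlr <- function(object, ...) object$coefficients

#' @export
predict.elicit_mlr <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  as.numeric(stats::predict(object$lm, newdata = newdata))
}

#' @export
residuals.elicit_mlr <- function(object, ...) as.numeric(stats::residuals(object$lm))

#' @export
print.elicit_mlr <- function(x, ...) {
  cat("Linear model of culture inputs",
      if (!is.na(x$alpha)) sprintf("(backward elimination, alpha = %g)", x$alpha)
      else "(full OLS)", "\n")
  tab <- data.frame(coefficient = x$coefficients,
                    std_error = x$standard_errors,
                    t_value = x$t_values, p_value = x$p_values)
  print(round(tab, 4))
  if (length(x$removed))
    cat("removed:", paste(x$removed, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
summary.elicit_mlr <- function(object, ...) {
  y <- object$lm$model$.response
  out <- list(fit = object,
              metrics = fit_metrics(y, as.numeric(stats::fitted(object$lm))),
              ranking = rank_terms_by_t(object))
  class(out) <- "summary.elicit_mlr"
  out
}

#' @export
print.summary.elicit_mlr <- function(x, ...) {
  print(x$fit)
  m <- x$metrics
  cat(sprintf("training fit: R2 %.4f, RMSE %.4f, MAPE %s, n %d\n",
              m$r2, m$rmse, if (is.na(m$mape)) "NA" else sprintf("%.2f%%", m$mape),
              m$n))
  cat("importance by |t|:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}
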