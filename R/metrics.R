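#' Goodness-of-fit statistics
#'
#' The three statistics used throughout the package to judge regression and
#' perceptron surrogates: coefficient of determination \eqn{R^2 = 1 -
#' SS_{res}/SS_{tot}}, root mean square error, and mean absolute percentage
#' error \eqn{MAPE = \frac{100}{n}\sum_i |(y_i - \hat y_i)/y_i|}.
#'
#' `rsq()` uses the residual-sum-of-squares definition about the mean of
#' `actual`, so it can be negative for models worse than the mean predictor;
#' off the training set it differs from squared Pearson correlation.
#'
#' @param actual numeric vector of observed values.
#' @param predicted numeric vector of model predictions, same length.
#' @return `mape()` a percentage; `rmse()` a value in response units;
#'   `rsq()` a unitless value \eqn{\le 1}; `fit_metrics()` a list with
#'   elements `r2`, `rmse`, `mape`, `n`.
#' @examples
#' mape(c(10, 20), c(9, 22))   # 10
#' rmse(c(0, 0), c(3, -4))     # sqrt(25/2)
#' @export
mape <- function(actual, predicted) {
  check_paired(actual, predicted)
  if (any(actual == 0))
    stopf("MAPE undefined: 'actual' contains zero values (division by zero)")
  mean(abs((actual - predicted) / actual)) * 100
}

#' @rdname mape
#' @export
rmse <- function(actual, predicted) {
  check_paired(actual, predicted)
  sqrt(mean((actual - predicted)^2))
}

#' @rdname mape
#' @export
rsq <- function(actual, predicted) {
  check_paired(actual, predicted)
  if (length(actual) < 2L) stopf("R^2 requires at least 2 observations")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stopf("R^2 undefined for a constant 'actual' vector")
  1 - sum((actual - predicted)^2) / ss_tot
}

#' @rdname mape
#' @export
fit_metrics <- function(actual, predicted) {
  list(
    r2 = rsq(actual, predicted),
    rmse = rmse(actual, predicted),
    mape = if (any(actual == 0)) NA_real_ else mape(actual, predicted),
    n = length(actual)
  )
}

check_paired <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stopf("'actual' and 'predicted' must have equal length (%d vs %d)",
          length(actual), length(predicted))
  if (length(actual) == 0L) stopf("empty input vectors")
  if (anyNA(actual) || anyNA(predicted)) stopf("NA values in input vectors")
  invisible(TRUE)
}
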