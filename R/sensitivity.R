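#' Variable sensitivity error of one input
#'
#' The model's RMSE when a given input is made unavailable. Unavailability is
#' implemented deterministically as mean-substitution: the column is replaced
#' by its mean over the evaluation rows and predictions are recomputed. An
#' alternative `"permute"` mode (random shuffling of the column) is provided
#' as an independent perturbation scheme for cross-checks.
#'
#' @param model a fitted `elicit_mlp`.
#' @param x,y evaluation inputs and observed response; conventionally all
#'   data rows (training and testing subsets together).
#' @param input column name or index of the input made unavailable.
#' @param mode `"mean"` (default) or `"permute"`.
#' @param seed RNG seed used by `"permute"` mode.
#' @return RMSE (response units) of the degraded model.
#' @export
vse <- function(model, x, y, input, mode = c("mean", "permute"), seed = NULL) {
  mode <- match.arg(mode)
  x <- as.data.frame(x)
  if (is.numeric(input)) {
    if (input < 1 || input > ncol(x)) stopf("input index out of range")
    input <- names(x)[input]
  }
  if (!input %in% names(x)) stopf("unknown input '%s'", input)
  x[[input]] <- switch(mode,
    mean = mean(x[[input]]),
    permute = with_seed(seed, sample(x[[input]])))
  rmse(y, predict(model, x, warn_extrapolation = FALSE))
}

#' Variable sensitivity ratio report
#'
#' Ranks the model inputs by importance. For each input the variable
#' sensitivity error (VSE, see [vse()]) is divided by the model's base RMSE
#' with all inputs available, giving the raw variable sensitivity ratio
#' (VSR, expected \eqn{\ge 1} for informative inputs). Raw ratios are then
#' rescaled to `[0, 1]` as \eqn{(VSR_i - 1)^+ / \max_j (VSR_j - 1)^+} — an
#' inert input maps to 0 and the most influential to 1 — and ranked by
#' descending scaled VSR (ties keep input order; the raw and scaled rankings
#' are identical because the rescaling is monotone).
#'
#' @inheritParams vse
#' @return object of class `sensitivity_report`: data frame with columns
#'   `input`, `vse`, `vsr_raw`, `vsr_scaled`, `rank`, plus attributes
#'   `base_rmse` and `n`.
#' @export
vsr_report <- function(model, x, y, mode = c("mean", "permute"), seed = NULL) {
  mode <- match.arg(mode)
  x <- as.data.frame(x)
  base <- rmse(y, predict(model, x, warn_extrapolation = FALSE))
  if (base == 0)
    stopf("degenerate model: base RMSE is 0, sensitivity ratios undefined")
  inputs <- if (inherits(model, "elicit_mlp")) model$input_names else names(x)
  errs <- vapply(inputs, function(v) vse(model, x, y, v, mode, seed),
                 numeric(1))
  raw <- errs / base
  excess <- pmax(raw - 1, 0)
  scaled <- if (max(excess) > 0) excess / max(excess) else excess
  ord <- order(-scaled)  # stable: ties keep input order
  rnk <- integer(length(inputs)); rnk[ord] <- seq_along(inputs)
  out <- data.frame(input = inputs, vse = errs, vsr_raw = raw,
                    vsr_scaled = scaled, rank = rnk, row.names = NULL)
  attr(out, "base_rmse") <- base
  attr(out, "n") <- length(y)
  attr(out, "mode") <- mode
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Input importance by variable sensitivity ratio (%s mode)\n",
              attr(x, "mode")))
  cat(sprintf("base RMSE %.4g on %d rows\n", attr(x, "base_rmse"), attr(x, "n")))
  df <- as.data.frame(x)
  df$vse <- signif(df$vse, 4); df$vsr_raw <- signif(df$vsr_raw, 4)
  df$vsr_scaled <- signif(df$vsr_scaled, 3)
  print(df[order(df$rank), ], row.names = FALSE)
  invisible(x)
}
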