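#' Blend composition of an optimal elicitor dose
#'
#' Summarizes a (CE dose, CF dose) pair the way culture optima are reported:
#' the total concentration (% v/v, 2 decimal places) and an integer blend
#' label such as `"90CE:10CF"`. The CE share is rounded half-up from the
#' unrounded dose ratio; the CF share is its complement, so the label always
#' totals 100.
#'
#' @param ce_conc,cf_conc elicitor doses, % v/v, non-negative.
#' @return list with `total_conc`, `ce_share`, `cf_share`, `label`.
#' @examples
#' blend_summary(5.67, 0.60)  # total 6.27, label "90CE:10CF"
#' @export
blend_summary <- function(ce_conc, cf_conc) {
  check_number(ce_conc, "ce_conc", lower = 0)
  check_number(cf_conc, "cf_conc", lower = 0)
  total <- round(ce_conc + cf_conc, 2)
  if (total == 0)
    return(list(total_conc = 0, ce_share = NA_integer_,
                cf_share = NA_integer_, label = "control"))
  ce_share <- as.integer(floor(100 * ce_conc / (ce_conc + cf_conc) + 0.5))
  cf_share <- 100L - ce_share
  list(total_conc = total, ce_share = ce_share, cf_share = cf_share,
       label = sprintf("%dCE:%dCF", ce_share, cf_share))
}

#' Elapsed time between elicitation and harvest
#'
#' @param adding_day,harvest_day culture days (may be fractional);
#'   `harvest_day >= adding_day`.
#' @return list with `hours` (numeric, `24 * (harvest_day - adding_day)`)
#'   and `text` (`"144 h"` or `"78 h and 29 min"`, minutes rounded).
#' @examples
#' elapsed_time(17, 23)$hours       # 144
#' elapsed_time(17, 20.27)$text     # "78 h and 29 min"
#' @export
elapsed_time <- function(adding_day, harvest_day) {
  check_number(adding_day, "adding_day")
  check_number(harvest_day, "harvest_day")
  if (harvest_day < adding_day)
    stopf("ordering error: harvest_day (%s) before adding_day (%s)",
          harvest_day, adding_day)
  hours <- 24 * (harvest_day - adding_day)
  h <- floor(hours)
  m <- round((hours - h) * 60)
  if (m == 60) { h <- h + 1; m <- 0 }
  text <- if (m == 0) sprintf("%d h", h) else sprintf("%d h and %d min", h, m)
  list(hours = hours, text = text)
}

#' Container for a culture-input optimum
#'
#' Bundles the optimal input vector found for one response with its predicted
#' value and the derived reporting quantities ([blend_summary()] and
#' [elapsed_time()]).
#'
#' @param response response name.
#' @param ce_conc,cf_conc,adding_day,harvest_day optimal input levels.
#' @param predicted predicted response at the optimum.
#' @param ga optional `ga_result` that produced the optimum.
#' @return object of class `optimization_result`.
#' @export
optimization_result <- function(response, ce_conc, cf_conc, adding_day,
                                harvest_day, predicted, ga = NULL) {
  blend <- blend_summary(ce_conc, cf_conc)
  elapsed <- elapsed_time(adding_day, harvest_day)
  structure(list(response = response,
                 inputs = c(ce_conc = ce_conc, cf_conc = cf_conc,
                            adding_day = adding_day, harvest_day = harvest_day),
                 predicted = predicted, blend = blend, elapsed = elapsed,
                 ga = ga),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  i <- x$inputs
  cat(sprintf("Optimal conditions for %s:\n", x$response))
  cat(sprintf(
    "  add %.2f%% (v/v) of %s (%.2f%% CE + %.2f%% CF) on day %.2f;\n",
    x$blend$total_conc, x$blend$label, i[["ce_conc"]], i[["cf_conc"]],
    i[["adding_day"]]))
  cat(sprintf("  harvest on day %.2f (%s after elicitation)\n",
              i[["harvest_day"]], x$elapsed$text))
  cat(sprintf("  predicted %s: %.2f\n", x$response, x$predicted))
  invisible(x)
}

# ---- portable estimator ------------------------------------------------------

ESTIMATOR_SCHEMA <- "elicit_mlp/1"

#' Export and reload a perceptron as a portable estimator file
#'
#' Writes the complete fitted model — weights, biases, min-max scalers,
#' activation tags and training metadata — to a self-contained JSON file so
#' predictions can be reproduced anywhere without refitting. `load_estimator`
#' validates the schema version and weight dimensions; a reloaded model
#' predicts identically to the original.
#'
#' @param model a fitted `elicit_mlp`.
#' @param path output file.
#' @return `export_estimator()` the path invisibly; `load_estimator()` an
#'   `elicit_mlp`.
#' @export
export_estimator <- function(model, path) {
  stopifnot(inherits(model, "elicit_mlp"))
  obj <- list(
    schema = ESTIMATOR_SCHEMA,
    n_hidden = model$n_hidden,
    input_names = model$input_names,
    input_min = model$input_scaler[1, ], input_max = model$input_scaler[2, ],
    target_min = model$target_scaler[1], target_max = model$target_scaler[2],
    hidden_weights = model$hidden_weights,  # row-major n_hidden x n_inputs
    hidden_biases = model$hidden_biases,
    output_weights = model$output_weights,
    output_bias = model$output_bias,
    activation = as.list(model$activation),
    training = list(seed = model$training$seed, epochs = model$training$epochs)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_estimator
#' @export
load_estimator <- function(path) {
  if (!file.exists(path)) stopf("estimator file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !identical(obj$schema, ESTIMATOR_SCHEMA))
    stopf("estimator schema mismatch: expected '%s', found '%s'",
          ESTIMATOR_SCHEMA, if (is.null(obj$schema)) "none" else obj$schema)
  h <- as.integer(obj$n_hidden)
  p <- length(obj$input_names)
  W1 <- matrix(as.numeric(obj$hidden_weights), nrow = h)
  if (!identical(dim(W1), c(h, p)) ||
      length(obj$hidden_biases) != h || length(obj$output_weights) != h)
    stopf("estimator validation error: weight dimensions inconsistent with n_hidden = %d, %d inputs",
          h, p)
  if (any(obj$input_min >= obj$input_max) || obj$target_min >= obj$target_max)
    stopf("estimator validation error: scaler min must be below max")
  structure(list(
    n_hidden = h,
    input_names = obj$input_names,
    input_scaler = rbind(as.numeric(obj$input_min), as.numeric(obj$input_max)),
    target_scaler = c(obj$target_min, obj$target_max),
    hidden_weights = W1,
    hidden_biases = as.numeric(obj$hidden_biases),
    output_weights = as.numeric(obj$output_weights),
    output_bias = as.numeric(obj$output_bias),
    activation = unlist(obj$activation),
    training = obj$training
  ), class = "elicit_mlp")
}

#' Closed-form prediction formula of a perceptron
#'
#' Renders the fitted network as a single arithmetic expression in the input
#' variable names (scaling, tanh hidden layer, linear output, inverse target
#' scaling) that any expression evaluator — a spreadsheet included — can
#' compute. Evaluating the string reproduces `predict()`.
#'
#' @param model a fitted `elicit_mlp`.
#' @return a single string.
#' @export
render_formula <- function(model) {
  stopifnot(inherits(model, "elicit_mlp"))
  rng <- model$input_scaler
  num <- function(v) sprintf("%.17g", v)
  scaled <- vapply(seq_along(model$input_names), function(j) {
    sprintf("(2*(%s - %s)/(%s) - 1)", model$input_names[j],
            num(rng[1, j]), num(rng[2, j] - rng[1, j]))
  }, character(1))
  hidden <- vapply(seq_len(model$n_hidden), function(i) {
    terms <- paste(sprintf("%s*%s", num(model$hidden_weights[i, ]), scaled),
                   collapse = " + ")
    sprintf("tanh(%s + %s)", terms, num(model$hidden_biases[i]))
  }, character(1))
  out_scaled <- paste0(
    paste(sprintf("%s*%s", num(model$output_weights), hidden), collapse = " + "),
    " + ", num(model$output_bias))
  tr <- model$target_scaler
  sprintf("((%s) + 1)/2*(%s) + %s", out_scaled, num(tr[2] - tr[1]), num(tr[1]))
}
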