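#' Run the full modeling-and-optimization workflow
#'
#' End-to-end orchestration for every response: simulate (or accept) an
#' experiment table, split it 70/30 into training and testing subsets, fit a
#' backward-elimination regression and a perceptron surrogate (hidden-layer
#' size chosen by evolutionary search on an inner validation split), evaluate
#' both families on both subsets, rank input importance by variable
#' sensitivity ratios on all rows, and maximize each perceptron over the
#' culture inputs with the genetic algorithm. All stages are seeded and
#' reproducible.
#'
#' @param data an experiment table (data frame with the standard columns);
#'   `NULL` simulates one from `design` and `params`.
#' @param design a [design_config()] used when `data` is `NULL`.
#' @param params a [surface_params()] used when `data` is `NULL`.
#' @param responses responses to model (default all five).
#' @param seed master seed; stage seeds are derived from it.
#' @param split_fraction training proportion of the random row split.
#' @param alpha significance level of the backward elimination.
#' @param n_hidden fixed hidden-layer size; `NULL` selects it per response
#'   via [select_architecture()] over `hidden_range`.
#' @param hidden_range candidate hidden-layer sizes for the search.
#' @param control a [mlp_control()].
#' @param arch_ga,opt_ga [ga_config()]s for the architecture search and the
#'   input optimization (seeds are overridden by derived stage seeds).
#' @param optimize run the input optimization stage.
#' @param out_dir optional directory: writes the data table (CSV), one
#'   estimator JSON per response, GA history CSVs and a report JSON.
#' @return object of class `run_report`: per-response list of fits, metrics,
#'   sensitivity and optimization results, plus a `comparison` data frame of
#'   regression vs perceptron test R-squared.
#' @examples
#' \donttest{
#' rep <- run_full_pipeline(seed = 1, responses = "total",
#'                          n_hidden = 6,
#'                          opt_ga = ga_config(generations = 100))
#' rep$comparison
#' }
#' @export
run_full_pipeline <- function(data = NULL,
                              design = design_config(),
                              params = surface_params(),
                              responses = TABLE_RESPONSES,
                              seed = 1,
                              split_fraction = 0.7,
                              alpha = 0.05,
                              n_hidden = NULL,
                              hidden_range = 2:10,
                              control = mlp_control(),
                              arch_ga = ga_config(population_size = 20,
                                                  generations = 10),
                              opt_ga = ga_config(),
                              optimize = TRUE,
                              out_dir = NULL) {
  responses <- match.arg(responses, TABLE_RESPONSES, several.ok = TRUE)
  check_number(seed, "seed")
  if (is.null(data)) data <- simulate_experiment(design, params, seed = seed)
  if (!all(c(TABLE_INPUTS, responses) %in% names(data)))
    stopf("data lacks required columns")
  X <- data[TABLE_INPUTS]
  split <- split_train_test(nrow(data), split_fraction, seed = seed + 1L)
  Xtr <- X[split$train, ]; Xte <- X[split$test, ]

  per_response <- list()
  comp <- NULL
  for (k in seq_along(responses)) {
    r <- responses[k]
    y <- data[[r]]
    if (anyNA(y)) stopf("stage split, response %s: missing response values", r)
    ytr <- y[split$train]; yte <- y[split$test]
    stage_seed <- seed + 10L * k

    reg <- tryCatch(backward_eliminate(Xtr, ytr, alpha = alpha),
                    error = function(e) stopf("stage regression, response %s: %s",
                                              r, conditionMessage(e)))
    reg_train <- evaluate_fit(reg, Xtr, ytr)
    reg_test <- evaluate_fit(reg, Xte, yte)

    if (is.null(n_hidden)) {
      arch_ga$seed <- stage_seed + 1L
      arch <- select_architecture(Xtr, ytr, hidden_range = hidden_range,
                                  control = control, config = arch_ga,
                                  seed = stage_seed + 2L)
      net <- arch$model
      chosen_hidden <- arch$n_hidden
      candidates <- arch$candidates
    } else {
      net <- mlp_fit(Xtr, ytr, n_hidden = n_hidden, control = control,
                     seed = stage_seed + 2L)
      chosen_hidden <- n_hidden
      candidates <- NULL
    }
    mlp_train <- evaluate_fit(net, Xtr, ytr)
    mlp_test <- evaluate_fit(net, Xte, yte)

    sens <- vsr_report(net, X, y)

    opt <- NULL
    if (optimize) {
      opt_ga$seed <- stage_seed + 3L
      # inputs observed at only a few settings (the adding day, typically)
      # are optimized over those settings; the surrogate has no data between
      snap <- lapply(X, function(v) {
        u <- sort(unique(v))
        if (length(u) <= 3) u else NULL
      })
      snap <- Filter(Negate(is.null), snap)
      opt <- optimize_inputs(net, config = opt_ga, response = r,
                             max_total_conc = max(X$ce_conc + X$cf_conc),
                             snap_levels = snap)
    }

    per_response[[r]] <- list(
      regression = reg,
      regression_metrics = list(train = reg_train, test = reg_test),
      mlp = net, n_hidden = chosen_hidden, candidates = candidates,
      mlp_metrics = list(train = mlp_train, test = mlp_test),
      sensitivity = sens,
      optimum = opt)
    comp <- rbind(comp, data.frame(
      response = r, n_hidden = chosen_hidden,
      reg_train_r2 = reg_train$r2, reg_test_r2 = reg_test$r2,
      mlp_train_r2 = mlp_train$r2, mlp_test_r2 = mlp_test$r2))
  }
  report <- structure(list(responses = per_response, comparison = comp,
                           split = split, seed = seed, n = nrow(data),
                           alpha = alpha, data = data),
                      class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Elicitation modeling run: %d observations (%d train / %d test), seed %d\n",
              x$n, length(x$split$train), length(x$split$test), x$seed))
  cat("\nRegression vs perceptron, test-subset R2:\n")
  comp <- x$comparison
  comp[-1] <- lapply(comp[-1], function(v) round(v, 3))
  print(comp, row.names = FALSE)
  for (r in names(x$responses)) {
    opt <- x$responses[[r]]$optimum
    if (!is.null(opt)) { cat("\n"); print(opt) }
  }
  invisible(x)
}

# Persist a run report: data CSV, per-response estimators + GA histories,
# and a JSON summary of every numeric result.
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_experiment(report$data, file.path(out_dir, "experiment.csv"))
  summary_obj <- list(seed = report$seed, n = report$n, alpha = report$alpha,
                      split = list(fraction = report$split$fraction,
                                   n_train = length(report$split$train),
                                   n_test = length(report$split$test)),
                      comparison = report$comparison, responses = list())
  for (r in names(report$responses)) {
    res <- report$responses[[r]]
    est_path <- file.path(out_dir, sprintf("estimator_%s.json", r))
    export_estimator(res$mlp, est_path)
    if (!is.null(res$optimum) && !is.null(res$optimum$ga))
      utils::write.csv(res$optimum$ga$history,
                       file.path(out_dir, sprintf("ga_history_%s.csv", r)),
                       row.names = FALSE)
    summary_obj$responses[[r]] <- list(
      regression = list(terms = res$regression$terms,
                        coefficients = res$regression$coefficients,
                        standard_errors = res$regression$standard_errors,
                        t_values = res$regression$t_values,
                        p_values = res$regression$p_values,
                        removed = res$regression$removed,
                        metrics = res$regression_metrics),
      mlp = list(n_hidden = res$n_hidden, estimator = basename(est_path),
                 metrics = res$mlp_metrics),
      sensitivity = as.data.frame(res$sensitivity),
      optimum = if (!is.null(res$optimum)) list(
        inputs = as.list(res$optimum$inputs),
        predicted = res$optimum$predicted,
        total_conc = res$optimum$blend$total_conc,
        blend_label = res$optimum$blend$label,
        elapsed_hours = res$optimum$elapsed$hours,
        elapsed_text = res$optimum$elapsed$text))
  }
  jsonlite::write_json(summary_obj, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
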