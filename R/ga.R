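#' Genetic-algorithm settings
#'
#' Defaults follow the evolutionary search configuration used for both the
#' hidden-layer size selection and the culture-input optimization: population
#' 50, crossover rate 0.85, 500 generations, mutation rate 0.01, roulette-
#' wheel (fitness-proportional) selection with one elite individual.
#'
#' @param population_size chromosomes per generation.
#' @param generations number of generations.
#' @param crossover_rate probability a selected pair undergoes arithmetic
#'   (blend) crossover.
#' @param mutation_rate per-gene probability of Gaussian mutation
#'   (sd = 10% of the gene's range, clipped to bounds).
#' @param elitism_count best individuals copied unchanged each generation.
#' @param seed RNG seed.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, generations = 500,
                      crossover_rate = 0.85, mutation_rate = 0.01,
                      elitism_count = 1, seed = NULL) {
  check_number(population_size, "population_size", lower = 2)
  check_number(generations, "generations", lower = 1)
  check_number(crossover_rate, "crossover_rate", lower = 0, upper = 1)
  check_number(mutation_rate, "mutation_rate", lower = 0, upper = 1)
  check_number(elitism_count, "elitism_count", lower = 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 selection = "roulette", seed = seed),
            class = "ga_config")
}

#' Maximize a fitness function with a real-coded genetic algorithm
#'
#' Chromosomes are real vectors within `bounds`. Each generation: fitness is
#' evaluated (an additive penalty proportional to total constraint violation
#' is subtracted for infeasible chromosomes); parents are drawn by roulette-
#' wheel selection on min-shifted penalized fitness; pairs undergo arithmetic
#' crossover with probability `crossover_rate` (per-gene convex blend);
#' per-gene Gaussian mutation (sd = 10% of the gene range) is applied with
#' probability `mutation_rate` and clipped to bounds; the `elitism_count`
#' best chromosomes survive unchanged, so the best penalized fitness is
#' non-decreasing across generations. Deterministic given `config$seed`.
#'
#' @param fitness function taking a decoded chromosome (numeric vector) and
#'   returning a finite scalar to maximize.
#' @param bounds list (or 2-row matrix) of `c(lower, upper)` per gene.
#' @param constraints optional list of functions `g(x)` that are `<= 0` when
#'   feasible; positive values are penalized in proportion.
#' @param config a [ga_config()].
#' @param penalty_weight multiplier on the summed constraint violation,
#'   scaled by the observed fitness spread.
#' @param vectorized if `TRUE`, `fitness` receives the whole population as a
#'   matrix (one chromosome per row) and returns a vector — one call per
#'   generation instead of one per chromosome.
#' @return object of class `ga_result`: `best_chromosome`, `best_fitness`
#'   (raw fitness of the best feasible-penalized chromosome), `history`
#'   (per-generation best and mean penalized fitness), `evaluations`.
#' @examples
#' r <- ga_optimize(function(x) -(x[1] - 3)^2, bounds = list(c(0, 10)),
#'                  config = ga_config(generations = 100, seed = 1))
#' r$best_chromosome
#' @export
ga_optimize <- function(fitness, bounds, constraints = list(),
                        config = ga_config(), penalty_weight = 10,
                        vectorized = FALSE) {
  stopifnot(inherits(config, "ga_config"))
  B <- do.call(rbind, lapply(bounds, function(b) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1] > b[2])
      stopf("each bound must be a finite c(lower, upper) pair")
    as.numeric(b)
  }))
  n_genes <- nrow(B)
  span <- B[, 2] - B[, 1]
  pop_n <- config$population_size

  # Penalty scale is frozen after the first evaluation so a chromosome's
  # penalized fitness never depends on the generation it is evaluated in
  # (this is what makes the elitist best-fitness trace provably monotone).
  pen_scale <- NULL
  eval_pop <- function(P) {
    raw <- if (vectorized) as.numeric(fitness(P)) else
      apply(P, 1, function(x) fitness(x))
    if (length(raw) != nrow(P) || !all(is.finite(raw)))
      stopf("fitness returned a non-finite or wrongly sized value")
    viol <- if (length(constraints)) {
      apply(P, 1, function(x)
        sum(vapply(constraints, function(g) max(0, g(x)), numeric(1))))
    } else numeric(nrow(P))
    if (is.null(pen_scale))
      pen_scale <<- max(diff(range(raw)), 1e-8)
    list(raw = raw, viol = viol,
         pen = raw - penalty_weight * pen_scale * viol)
  }

  with_seed(config$seed, {
    # initial population: uniform in the box; prefer feasible chromosomes
    P <- t(B[, 1] + t(matrix(stats::runif(pop_n * n_genes), pop_n, n_genes)) * span)
    if (length(constraints)) {
      feasible <- function(x)
        all(vapply(constraints, function(g) g(x) <= 0, logical(1)))
      ok <- apply(P, 1, feasible)
      tries <- 0L
      while (!any(ok) && tries < 100L) {
        P <- t(B[, 1] + t(matrix(stats::runif(pop_n * n_genes), pop_n, n_genes)) * span)
        ok <- apply(P, 1, feasible)
        tries <- tries + 1L
      }
      if (!any(ok))
        stopf("constraint error: no feasible chromosome found in 100 resampling attempts")
    }
    ev <- eval_pop(P)
    n_eval <- pop_n
    hist_best <- numeric(config$generations)
    hist_mean <- numeric(config$generations)
    # best strictly feasible chromosome seen anywhere in the run; preferred
    # over the best penalized one so returned optima satisfy constraints
    # exactly rather than up to the penalty trade-off
    best_feas <- NULL; best_feas_fit <- -Inf
    note_feasible <- function() {
      i <- which(ev$viol == 0)
      if (length(i)) {
        j <- i[which.max(ev$raw[i])]
        if (ev$raw[j] > best_feas_fit) {
          best_feas_fit <<- ev$raw[j]
          best_feas <<- P[j, ]
        }
      }
    }
    note_feasible()

    for (gen in seq_len(config$generations)) {
      ord <- order(ev$pen, decreasing = TRUE)
      # roulette wheel on min-shifted penalized fitness
      w <- ev$pen - min(ev$pen) + 1e-9 * max(1, abs(min(ev$pen)))
      prob <- w / sum(w)
      parents <- sample.int(pop_n, pop_n, replace = TRUE, prob = prob)
      Q <- P[parents, , drop = FALSE]

      # arithmetic crossover on consecutive pairs
      for (i in seq(1, pop_n - 1, by = 2)) {
        if (stats::runif(1) < config$crossover_rate) {
          u <- stats::runif(n_genes)
          a <- Q[i, ]; b <- Q[i + 1, ]
          Q[i, ] <- u * a + (1 - u) * b
          Q[i + 1, ] <- (1 - u) * a + u * b
        }
      }
      # Gaussian mutation, clipped to bounds
      mut <- matrix(stats::runif(pop_n * n_genes) < config$mutation_rate,
                    pop_n, n_genes)
      if (any(mut)) {
        noise <- matrix(stats::rnorm(pop_n * n_genes, 0,
                                     rep(0.1 * pmax(span, 1e-12), each = pop_n)),
                        pop_n, n_genes)
        Q[mut] <- Q[mut] + noise[mut]
        Q <- pmin(pmax(Q, matrix(B[, 1], pop_n, n_genes, byrow = TRUE)),
                  matrix(B[, 2], pop_n, n_genes, byrow = TRUE))
      }
      # elitism: overwrite the first slots with the current best
      k <- min(config$elitism_count, pop_n)
      if (k > 0) Q[seq_len(k), ] <- P[ord[seq_len(k)], , drop = FALSE]
      P <- Q
      ev <- eval_pop(P)
      n_eval <- n_eval + pop_n
      hist_best[gen] <- max(ev$pen)
      hist_mean[gen] <- mean(ev$pen)
      note_feasible()
    }
    ord <- order(ev$pen, decreasing = TRUE)
    best <- P[ord[1], ]
    best_fit <- ev$raw[ord[1]]
    if (!is.null(best_feas)) {
      best <- best_feas
      best_fit <- best_feas_fit
    }
    structure(list(best_chromosome = as.numeric(best),
                   best_fitness = best_fit,
                   best_penalized = ev$pen[ord[1]],
                   history = data.frame(generation = seq_len(config$generations),
                                        best = hist_best, mean = hist_mean),
                   evaluations = n_eval, config = config),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA result: best fitness %.6g after %d evaluations\n",
              x$best_fitness, x$evaluations))
  cat("best chromosome:", paste(signif(x$best_chromosome, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Fitness trace of a genetic-algorithm run
#' @param x a `ga_result`.
#' @param ... passed to [plot()].
#' @export
plot.ga_result <- function(x, ...) {
  plot(x$history$generation, x$history$best, type = "l",
       xlab = "generation", ylab = "penalized fitness",
       main = "GA convergence", ...)
  graphics::lines(x$history$generation, x$history$mean, lty = 2)
  graphics::legend("bottomright", c("best", "mean"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Evolutionary selection of the hidden-layer size
#'
#' Runs an integer-gene genetic algorithm (a real gene rounded to the nearest
#' count) over `hidden_range`; the fitness of a candidate size is the
#' negative RMSE on an inner validation split carved from the training rows
#' only (never the test subset), with a fixed training seed per candidate so
#' the search is deterministic, and candidate evaluations cached. The winner
#' is retrained on all training rows.
#'
#' @param x,y training inputs and response.
#' @param hidden_range integer vector of candidate hidden-unit counts.
#' @param control a [mlp_control()] for candidate training.
#' @param config a [ga_config()]; heavy defaults are unnecessary here since
#'   there are few distinct candidates.
#' @param inner_fraction fraction of the training rows held out to score
#'   candidates.
#' @param seed seed for the inner split and candidate training.
#' @return list with `n_hidden`, `model` (retrained on all rows), and
#'   `candidates` (data frame of evaluated sizes and their validation RMSE).
#' @export
select_architecture <- function(x, y, hidden_range = 1:15,
                                control = mlp_control(),
                                config = ga_config(generations = 30),
                                inner_fraction = 0.15, seed = 1) {
  if (!length(hidden_range)) stopf("'hidden_range' is empty")
  hidden_range <- sort(unique(as.integer(hidden_range)))
  x <- as.data.frame(x)
  if (length(hidden_range) == 1L) {
    model <- mlp_fit(x, y, n_hidden = hidden_range, control = control,
                     seed = seed)
    return(list(n_hidden = hidden_range, model = model,
                candidates = data.frame(n_hidden = hidden_range,
                                        val_rmse = NA_real_)))
  }
  n <- nrow(x)
  idx_val <- with_seed(seed, sort(sample.int(n, max(1L, round(inner_fraction * n)))))
  idx_tr <- setdiff(seq_len(n), idx_val)

  cache <- new.env(parent = emptyenv())
  score <- function(h) {
    key <- as.character(h)
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- mlp_fit(x[idx_tr, , drop = FALSE], y[idx_tr], n_hidden = h,
                 control = control, seed = seed)
    v <- rmse(y[idx_val],
              predict(m, x[idx_val, , drop = FALSE], warn_extrapolation = FALSE))
    cache[[key]] <- v
    v
  }
  res <- ga_optimize(
    fitness = function(g) -score(round_to_range(g[1], hidden_range)),
    bounds = list(range(hidden_range) + c(-0.49, 0.49)),
    config = config)
  evaluated <- sort(as.integer(ls(cache)))
  cand <- data.frame(n_hidden = evaluated,
                     val_rmse = vapply(as.character(evaluated),
                                       function(k) cache[[k]], numeric(1)))
  best_h <- cand$n_hidden[which.min(cand$val_rmse)]
  model <- mlp_fit(x, y, n_hidden = best_h, control = control, seed = seed)
  list(n_hidden = best_h, model = model, candidates = cand)
}

round_to_range <- function(g, values) {
  h <- as.integer(round(g))
  values[which.min(abs(values - h))]
}

#' Optimize culture inputs over a fitted surrogate
#'
#' Maximizes the surrogate's predicted response over (CE dose, CF dose,
#' adding day, harvest day) within `bounds`, subject to harvesting after
#' elicitation (`harvest_day >= adding_day`) and, when `max_total_conc` is
#' given, to the total elicitor dose `ce_conc + cf_conc <= max_total_conc`.
#' Bounds default to the model's training ranges. The dose cap matters
#' because factorial blend designs sample the doses on the simplex
#' `ce + cf = concentration`: the high-CE high-CF corner of the box is never
#' observed, and a surrogate queried there is extrapolating; capping the
#' total dose at the largest concentration in the training data keeps the
#' search inside the region the data support.
#'
#' @param model a fitted `elicit_mlp` (or any object with a `predict` method
#'   on the four input columns).
#' @param bounds named list of `c(lower, upper)` for the four inputs;
#'   `NULL` uses the model's training ranges.
#' @param config a [ga_config()].
#' @param response response name recorded in the result.
#' @param max_total_conc cap on `ce_conc + cf_conc` (% v/v); `NULL` disables.
#' @param snap_levels named list of allowed values for inputs that should be
#'   searched over a discrete level set instead of a continuous interval
#'   (e.g. `list(adding_day = c(13, 17))`). A surrogate carries no data
#'   between the levels of an input observed at only a few settings, so its
#'   interior behaviour there is arbitrary; snapping keeps the optimum on
#'   settings the experiment actually sampled.
#' @return an [optimization_result()] with the optimal inputs, the predicted
#'   optimum and derived blend/timing quantities.
#' @export
optimize_inputs <- function(model, bounds = NULL, config = ga_config(),
                            response = "response", max_total_conc = NULL,
                            snap_levels = NULL) {
  if (is.null(bounds)) {
    if (!inherits(model, "elicit_mlp"))
      stopf("'bounds' is required unless the model stores training ranges")
    rng <- model$input_scaler
    bounds <- stats::setNames(lapply(seq_len(ncol(rng)), function(j) rng[, j]),
                              model$input_names)
  }
  if (!all(TABLE_INPUTS %in% names(bounds)))
    stopf("bounds must name %s", paste(TABLE_INPUTS, collapse = ", "))
  bounds <- bounds[TABLE_INPUTS]
  snap <- function(P) {
    for (nm in names(snap_levels)) {
      j <- match(nm, TABLE_INPUTS)
      lv <- sort(snap_levels[[nm]])
      P[, j] <- lv[pmax(1L, findInterval(P[, j], lv + c(diff(lv) / 2, Inf)) + 1L)]
    }
    P
  }
  predict_pop <- function(P) {
    nd <- as.data.frame(snap(P))
    names(nd) <- TABLE_INPUTS
    if (inherits(model, "elicit_mlp"))
      predict(model, nd, warn_extrapolation = FALSE)
    else predict(model, nd)
  }
  snap1 <- function(x) drop(snap(matrix(x, 1)))
  # constraints act on the snapped (reported) inputs
  constraints <- list(function(x) { s <- snap1(x); s[3] - s[4] })
  if (!is.null(max_total_conc)) {
    check_number(max_total_conc, "max_total_conc", lower = 0)
    constraints <- c(constraints,
                     function(x) { s <- snap1(x); s[1] + s[2] - max_total_conc })
  }
  res <- ga_optimize(
    fitness = predict_pop,
    bounds = bounds,
    constraints = constraints,
    config = config,
    vectorized = TRUE)
  xb <- stats::setNames(snap1(res$best_chromosome), TABLE_INPUTS)
  optimization_result(response = response,
                      ce_conc = xb[["ce_conc"]], cf_conc = xb[["cf_conc"]],
                      adding_day = xb[["adding_day"]],
                      harvest_day = xb[["harvest_day"]],
                      predicted = res$best_fitness, ga = res)
}
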