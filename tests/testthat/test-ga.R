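test_that("the GA solves a 1-D quadratic and its elitist trace is monotone", {
  r <- ga_optimize(function(x) -(x[1] - 3)^2, bounds = list(c(0, 10)),
                   config = ga_config(seed = 1))
  expect_lt(abs(r$best_chromosome - 3), 0.05)
  expect_false(is.unsorted(r$history$best))
  expect_equal(r$evaluations, 50 * 501)
})

test_that("the GA matches a dense grid oracle on a 2-D bump across seeds", {
  fitness <- function(x) exp(-((x[1] - 4)^2 + (x[2] - 5)^2) / 6) +
    0.3 * exp(-((x[1] - 8)^2 + (x[2] - 1)^2) / 2)
  g <- expand.grid(x = seq(0, 10, 0.1), y = seq(0, 10, 0.1))
  gv <- mapply(function(a, b) fitness(c(a, b)), g$x, g$y)
  grid_opt <- unlist(g[which.max(gv), ])
  hits <- 0
  for (seed in 1:10) {
    r <- ga_optimize(fitness, bounds = list(c(0, 10), c(0, 10)),
                     config = small_ga(seed, generations = 200))
    if (all(abs(r$best_chromosome - grid_opt) <= 0.1)) hits <- hits + 1
    expect_false(is.unsorted(r$history$best))
  }
  expect_gte(hits, 9)
})

test_that("constrained optima are feasible", {
  # unconstrained optimum (10, 0) violates x1 <= x2
  r <- ga_optimize(function(x) x[1] - 0.1 * x[2],
                   bounds = list(c(0, 10), c(0, 10)),
                   constraints = list(function(x) x[1] - x[2]),
                   config = ga_config(seed = 3))
  expect_lte(r$best_chromosome[1], r$best_chromosome[2] + 1e-6)
  # the constrained optimum lies along x1 = x2 at the high end of the box
  expect_gt(r$best_chromosome[1], 7)
  expect_lt(r$best_chromosome[2] - r$best_chromosome[1], 1)
})

test_that("an all-infeasible constraint set is reported", {
  expect_error(
    ga_optimize(function(x) x[1], bounds = list(c(0, 1)),
                constraints = list(function(x) 1),  # never feasible
                config = ga_config(seed = 1, generations = 2)),
    "feasible")
})

test_that("roulette selection weights are a probability distribution", {
  # exercised indirectly: fitness spanning negative values must still work
  r <- ga_optimize(function(x) -1000 - (x[1] - 2)^2, bounds = list(c(0, 5)),
                   config = small_ga(2, generations = 150))
  expect_lt(abs(r$best_chromosome - 2), 0.05)
})

test_that("architecture search prefers parsimonious networks on linear data", {
  set.seed(6)
  x <- as.data.frame(matrix(runif(400, 0, 1), 100, 4))
  names(x) <- TABLE_INPUTS
  y <- 2 * x$ce_conc - x$cf_conc + 0.5 * x$adding_day
  sel <- select_architecture(x, y, hidden_range = 1:6,
                             control = fast_control(10000, 1500),
                             config = small_ga(4, generations = 12,
                                               population_size = 12),
                             seed = 4)
  cand <- sel$candidates
  best_small <- min(cand$val_rmse[cand$n_hidden <= 3])
  expect_lte(best_small, min(cand$val_rmse) + 1e-3 * diff(range(y)))
})

test_that("a singleton hidden range is returned without search", {
  set.seed(7)
  x <- as.data.frame(matrix(runif(200, 0, 1), 50, 4))
  names(x) <- TABLE_INPUTS
  y <- x$ce_conc + rnorm(50, 0, 0.05)
  sel <- select_architecture(x, y, hidden_range = 4,
                             control = fast_control(300, 50), seed = 1)
  expect_equal(sel$n_hidden, 4)
  expect_equal(sel$model$n_hidden, 4L)
})

test_that("input optimization respects degenerate and constrained regions", {
  d <- simulate_experiment(params = surface_params(seed = 30))
  fit <- mlp_fit(d[TABLE_INPUTS], d$portion, n_hidden = 5, seed = 3,
                 control = fast_control())
  # collapsed bounds: that point is returned with its prediction
  pt <- list(ce_conc = c(2, 2), cf_conc = c(3, 3),
             adding_day = c(13, 13), harvest_day = c(19, 19))
  o <- optimize_inputs(fit, bounds = pt, config = small_ga(5, generations = 5),
                       response = "portion")
  expect_equal(unname(o$inputs), c(2, 3, 13, 19), tolerance = 1e-9)
  expect_equal(o$predicted,
               predict(fit, data.frame(ce_conc = 2, cf_conc = 3,
                                       adding_day = 13, harvest_day = 19)))
  # secretion share grows with harvest day: boundary optimum at the last day
  o2 <- optimize_inputs(fit, config = ga_config(seed = 6, generations = 150),
                        response = "portion", max_total_conc = 10)
  expect_gte(o2$inputs[["harvest_day"]], 22)
  expect_lte(o2$inputs[["ce_conc"]] + o2$inputs[["cf_conc"]], 10 + 1e-6)
  expect_gte(o2$inputs[["harvest_day"]], o2$inputs[["adding_day"]])
  # discrete inputs are optimized over their observed settings only
  o3 <- optimize_inputs(fit, config = ga_config(seed = 7, generations = 100),
                        response = "portion", max_total_conc = 10,
                        snap_levels = list(adding_day = c(13, 17)))
  expect_true(o3$inputs[["adding_day"]] %in% c(13, 17))
  expect_gte(o3$inputs[["harvest_day"]], o3$inputs[["adding_day"]])
})
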