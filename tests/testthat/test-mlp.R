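test_that("forward pass matches hand evaluation on tiny networks", {
  # all weights zero: every prediction is the inverse-scaled output bias
  m0 <- identity_mlp(W1 = matrix(0, 2, 3), b1 = c(0, 0), w2 = c(0, 0), b2 = 0.4)
  x <- data.frame(x1 = c(-1, 0.2), x2 = c(0.5, 1), x3 = c(0, -0.7))
  expect_equal(predict(m0, x), rep(0.4, 2))
  # one hidden unit, unit weights: tanh passes straight through
  m1 <- identity_mlp(W1 = matrix(1, 1, 1), b1 = 0, w2 = 1, b2 = 0,
                     input_names = "x1")
  expect_equal(predict(m1, data.frame(x1 = 0.5)), tanh(0.5))
  expect_equal(predict(m1, data.frame(x1 = -0.25)), tanh(-0.25))
})

test_that("analytic gradients match central finite differences", {
  set.seed(14)
  for (i in 1:4) {
    n <- 12; p <- sample(2:4, 1); h <- sample(1:4, 1)
    Xs <- matrix(runif(n * p, -1, 1), n, p)
    ys <- runif(n, -1, 1)
    par <- runif(elicitopt:::mlp_npar(h, p), -0.5, 0.5)
    g <- elicitopt:::mlp_loss_grad(par, Xs, ys, h)
    eps <- 1e-6
    num <- vapply(seq_along(par), function(j) {
      pp <- par; pp[j] <- pp[j] + eps
      pm <- par; pm[j] <- pm[j] - eps
      (elicitopt:::mlp_loss_grad(pp, Xs, ys, h)$loss -
         elicitopt:::mlp_loss_grad(pm, Xs, ys, h)$loss) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(g$grad - num)) / max(abs(num), 1e-8), 1e-5)
  }
})

test_that("scaling round-trips on training ranges", {
  rng <- c(-3.2, 17.9)
  x <- seq(rng[1], rng[2], length.out = 11)
  expect_equal(elicitopt:::unscale_minmax(elicitopt:::scale_minmax(x, rng), rng),
               x, tolerance = 1e-12)
})

test_that("the perceptron reproduces a noiseless linear map", {
  set.seed(3)
  x <- as.data.frame(matrix(runif(80, 0, 10), 20, 4))
  names(x) <- TABLE_INPUTS
  y <- 1 + 2 * x$ce_conc - 0.5 * x$cf_conc + 0.1 * x$adding_day
  fit <- mlp_fit(x, y, n_hidden = 3, seed = 5,
                 control = mlp_control(val_fraction = 0))
  expect_gte(rsq(y, predict(fit, x)), 0.999)
})

test_that("training is deterministic given data and seed", {
  d <- simulate_experiment(params = surface_params(seed = 1))[1:100, ]
  f1 <- mlp_fit(d[TABLE_INPUTS], d$intra, n_hidden = 4, seed = 9,
                control = fast_control(800, 100))
  f2 <- mlp_fit(d[TABLE_INPUTS], d$intra, n_hidden = 4, seed = 9,
                control = fast_control(800, 100))
  expect_identical(f1$hidden_weights, f2$hidden_weights)
  expect_identical(f1$output_weights, f2$output_weights)
  f3 <- mlp_fit(d[TABLE_INPUTS], d$intra, n_hidden = 4, seed = 10,
                control = fast_control(800, 100))
  expect_false(identical(f1$hidden_weights, f3$hidden_weights))
})

test_that("accepted training error is non-increasing within the growth tolerance", {
  d <- simulate_experiment(params = surface_params(seed = 4))[1:200, ]
  fit <- mlp_fit(d[TABLE_INPUTS], d$total, n_hidden = 5, seed = 2,
                 control = fast_control(1500, 1500))
  h <- fit$training$loss_history
  ratio <- h[-1] / h[-length(h)]
  expect_true(all(ratio <= fit$training$control$max_error_growth + 1e-12))
})

test_that("formula interface and the X/y interface agree", {
  d <- simulate_experiment(params = surface_params(seed = 2))[1:150, ]
  fa <- mlp_fit(dw ~ ce_conc + cf_conc + adding_day + harvest_day, data = d,
                n_hidden = 3, seed = 1, control = fast_control(500, 100))
  fb <- mlp_fit(d[TABLE_INPUTS], d$dw, n_hidden = 3, seed = 1,
                control = fast_control(500, 100))
  expect_equal(fa$hidden_weights, fb$hidden_weights)
})

test_that("out-of-range inputs warn but still predict", {
  d <- simulate_experiment(params = surface_params(seed = 2))[1:100, ]
  fit <- mlp_fit(d[TABLE_INPUTS], d$dw, n_hidden = 2, seed = 1,
                 control = fast_control(300, 50))
  far <- data.frame(ce_conc = 50, cf_conc = 0, adding_day = 13, harvest_day = 23)
  expect_warning(p <- predict(fit, far), "extrapolation")
  expect_true(is.finite(p))
})

test_that("evaluation metrics are row-order invariant and null under shuffling", {
  d <- simulate_experiment(params = surface_params(seed = 20))
  s <- split_train_test(d, 0.7, seed = 20)
  fit <- mlp_fit(d[s$train, TABLE_INPUTS], d$total[s$train], n_hidden = 5,
                 seed = 3, control = fast_control())
  te <- s$test
  m1 <- evaluate_fit(fit, d[te, TABLE_INPUTS], d$total[te])
  perm <- sample(length(te))
  m2 <- evaluate_fit(fit, d[te[perm], TABLE_INPUTS], d$total[te[perm]])
  expect_equal(m1$rmse, m2$rmse)
  expect_equal(m1$r2, m2$r2)
  # shuffled responses: no predictive information left
  set.seed(1)
  m3 <- evaluate_fit(fit, d[te, TABLE_INPUTS], sample(d$total[te]))
  expect_lt(m3$r2, 0.2)
})

test_that("degenerate inputs are rejected with clear messages", {
  full <- simulate_experiment(params = surface_params(seed = 2))
  set.seed(1)
  d <- full[sample(nrow(full), 50), ]
  x <- d[TABLE_INPUTS]; x$ce_conc <- 1
  expect_error(mlp_fit(x, d$dw, n_hidden = 2), "constant input")
  expect_error(mlp_fit(d[TABLE_INPUTS], rep(1, 50), n_hidden = 2),
               "constant response")
  expect_error(mlp_fit(d[1:5, TABLE_INPUTS], d$dw[1:5], n_hidden = 2),
               "at least 10")
})
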