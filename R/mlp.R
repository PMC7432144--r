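#' Training controls for the perceptron
#'
#' Full-batch back-propagation with momentum and an adaptive learning rate:
#' after each proposed weight update the batch error is re-evaluated; a step
#' that would grow the error by more than `max_error_growth` is rejected (the
#' learning rate shrinks by `lr_decrease` and the momentum memory is reset),
#' otherwise it is accepted and, on improvement, the learning rate grows by
#' `lr_increase`. Early stopping monitors an internal validation split of the
#' training rows; the weights returned are the best-validation snapshot.
#'
#' @param learning_rate initial step size on the scaled error surface.
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param max_epochs maximum number of full-batch epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param val_fraction fraction of training rows held out for early stopping
#'   (0 disables early stopping; the final weights are returned).
#' @param lr_increase,lr_decrease,max_error_growth adaptive-rate constants.
#' @return list of class `mlp_control`.
#' @export
mlp_control <- function(learning_rate = 0.05, momentum = 0.9,
                        max_epochs = 12000, patience = 1200,
                        val_fraction = 0.15, lr_increase = 1.05,
                        lr_decrease = 0.7, max_error_growth = 1.04) {
  check_number(learning_rate, "learning_rate", lower = 1e-12)
  check_number(momentum, "momentum", lower = 0, upper = 1 - 1e-9)
  check_number(max_epochs, "max_epochs", lower = 1)
  check_number(val_fraction, "val_fraction", lower = 0, upper = 0.9)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, lr_increase = lr_increase,
                 lr_decrease = lr_decrease, max_error_growth = max_error_growth),
            class = "mlp_control")
}

# ---- parameter packing ------------------------------------------------------

mlp_npar <- function(n_hidden, n_in) n_hidden * n_in + n_hidden + n_hidden + 1L

mlp_unpack <- function(par, n_hidden, n_in) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(n_hidden * n_in)], n_hidden, n_in)
  i <- i + n_hidden * n_in
  b1 <- par[i + seq_len(n_hidden)]; i <- i + n_hidden
  w2 <- par[i + seq_len(n_hidden)]; i <- i + n_hidden
  b2 <- par[i + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

# Forward pass on already-scaled inputs; returns scaled predictions.
mlp_forward_scaled <- function(w, Xs) {
  H <- tanh(Xs %*% t(w$W1) + matrix(w$b1, nrow(Xs), length(w$b1), byrow = TRUE))
  as.numeric(H %*% w$w2 + w$b2)
}

# Batch MSE and its analytic gradient w.r.t. the packed parameter vector.
mlp_loss_grad <- function(par, Xs, ys, n_hidden) {
  n_in <- ncol(Xs); n <- nrow(Xs)
  w <- mlp_unpack(par, n_hidden, n_in)
  Z <- Xs %*% t(w$W1) + matrix(w$b1, n, n_hidden, byrow = TRUE)
  H <- tanh(Z)
  yhat <- as.numeric(H %*% w$w2 + w$b2)
  e <- yhat - ys
  loss <- mean(e^2)
  d_out <- 2 * e / n                     # dL/dyhat
  g_b2 <- sum(d_out)
  g_w2 <- as.numeric(crossprod(H, d_out))
  dZ <- (d_out %*% t(w$w2)) * (1 - H^2)  # back through tansig
  g_b1 <- colSums(dZ)
  g_W1 <- crossprod(dZ, Xs)              # n_hidden x n_in
  list(loss = loss, grad = c(as.numeric(g_W1), g_b1, g_w2, g_b2))
}

scale_minmax <- function(x, rng) 2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
unscale_minmax <- function(s, rng) (s + 1) / 2 * (rng[2] - rng[1]) + rng[1]

# ---- fitting ----------------------------------------------------------------

#' Fit a three-layer perceptron surrogate
#'
#' A feed-forward network with one hidden layer of hyperbolic-tangent
#' (tansig) units and a single linear (purelin) output, trained by full-batch
#' back-propagation on the mean squared error of min-max scaled targets (see
#' [mlp_control()] for the update rule). Inputs and target are scaled to
#' `[-1, 1]` using the training-data ranges; the scalers are stored in the
#' model and applied transparently by `predict()`. Weights are initialized
#' uniformly in `[-0.5, 0.5]` from `seed`; training is deterministic given
#' data and seed.
#'
#' @param x predictor data frame/matrix, or a formula.
#' @param y numeric response (ignored when `x` is a formula).
#' @param data data frame supplying formula variables.
#' @param n_hidden number of hidden tansig units.
#' @param control a [mlp_control()].
#' @param seed RNG seed for weight initialization and the validation split.
#' @param ... unused.
#' @return object of class `elicit_mlp` with the weight matrices, scaler
#'   ranges, activation tags and training metadata.
#' @examples
#' d <- simulate_experiment(params = surface_params(seed = 7))
#' s <- split_train_test(d, 0.7, seed = 7)
#' fit <- mlp_fit(total ~ ce_conc + cf_conc + adding_day + harvest_day,
#'                data = d[s$train, ], n_hidden = 6, seed = 7)
#' pred <- predict(fit, d[s$test, ])
#' @export
mlp_fit <- function(x, y = NULL, data = NULL, n_hidden = 8,
                    control = mlp_control(), seed = 1, ...) {
  if (inherits(x, "formula")) {
    mf <- stats::model.frame(x, data = data)
    y <- stats::model.response(mf)
    x <- mf[-1L]
  }
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stopf("nrow(x) != length(y)")
  if (anyNA(x) || anyNA(y)) stopf("NA values in training data")
  if (nrow(x) < 10L) stopf("need at least 10 training rows")
  check_number(n_hidden, "n_hidden", lower = 1)
  n_hidden <- as.integer(n_hidden)
  stopifnot(inherits(control, "mlp_control"))

  in_rng <- apply(x, 2, range)
  if (any(in_rng[1, ] == in_rng[2, ]))
    stopf("constant input column(s): %s",
          paste(colnames(x)[in_rng[1, ] == in_rng[2, ]], collapse = ", "))
  out_rng <- range(y)
  if (out_rng[1] == out_rng[2]) stopf("constant response")
  Xs <- sapply(seq_len(ncol(x)), function(j) scale_minmax(x[, j], in_rng[, j]))
  Xs <- matrix(Xs, nrow(x), ncol(x))
  ys <- scale_minmax(y, out_rng)

  n <- nrow(Xs)
  n_val <- if (control$val_fraction > 0) max(1L, as.integer(round(control$val_fraction * n))) else 0L
  fit <- with_seed(seed, {
    idx_val <- if (n_val > 0L) sort(sample.int(n, n_val)) else integer()
    idx_tr <- setdiff(seq_len(n), idx_val)
    par <- stats::runif(mlp_npar(n_hidden, ncol(x)), -0.5, 0.5)
    train_mlp_loop(par, Xs, ys, idx_tr, idx_val, n_hidden, control)
  })
  if (!is.finite(fit$loss))
    stopf("training diverged (error is not finite); try a smaller learning_rate")

  w <- mlp_unpack(fit$par, n_hidden, ncol(x))
  structure(list(
    n_hidden = n_hidden,
    input_names = colnames(x),
    input_scaler = in_rng,            # 2 x p matrix: row 1 min, row 2 max
    target_scaler = out_rng,
    hidden_weights = w$W1, hidden_biases = w$b1,
    output_weights = w$w2, output_bias = w$b2,
    activation = c(hidden = "tansig", output = "purelin"),
    training = list(epochs = fit$epochs, seed = seed, control = control,
                    final_loss = fit$loss, val_loss = fit$val_loss,
                    loss_history = fit$history, n_train = length(fit$idx_tr),
                    n_val = n_val)
  ), class = "elicit_mlp")
}

train_mlp_loop <- function(par, Xs, ys, idx_tr, idx_val, n_hidden, control) {
  Xtr <- Xs[idx_tr, , drop = FALSE]; ytr <- ys[idx_tr]
  Xva <- Xs[idx_val, , drop = FALSE]; yva <- ys[idx_val]
  lr <- control$learning_rate
  vel <- numeric(length(par))
  cur <- mlp_loss_grad(par, Xtr, ytr, n_hidden)
  best_par <- par
  val_loss <- function(p) {
    if (!length(idx_val)) return(NA_real_)
    w <- mlp_unpack(p, n_hidden, ncol(Xs))
    mean((mlp_forward_scaled(w, Xva) - yva)^2)
  }
  best_val <- val_loss(par)
  since_best <- 0L
  history <- numeric(0)
  epoch <- 0L
  while (epoch < control$max_epochs) {
    epoch <- epoch + 1L
    vel <- control$momentum * vel - lr * cur$grad
    cand <- par + vel
    new <- mlp_loss_grad(cand, Xtr, ytr, n_hidden)
    if (!is.finite(new$loss) || new$loss > cur$loss * control$max_error_growth) {
      lr <- lr * control$lr_decrease
      vel[] <- 0
      if (lr < 1e-12) break
      epoch <- epoch - 1L  # rejected proposal, retry the epoch
      next
    }
    if (new$loss < cur$loss) lr <- min(lr * control$lr_increase, 10)
    par <- cand; cur <- new
    history <- c(history, cur$loss)
    if (length(idx_val)) {
      v <- val_loss(par)
      if (is.na(best_val) || v < best_val) {
        best_val <- v; best_par <- par; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= control$patience) break
      }
    } else {
      best_par <- par
    }
  }
  list(par = best_par, loss = cur$loss, val_loss = best_val,
       epochs = epoch, history = history, idx_tr = idx_tr)
}

# ---- methods ----------------------------------------------------------------

#' Predict from a fitted perceptron
#'
#' Applies the stored min-max scalers, the tansig hidden layer and the linear
#' output. Inputs outside the training range are allowed but trigger an
#' extrapolation warning.
#'
#' @param object an `elicit_mlp` model.
#' @param newdata data frame or matrix with the model's input columns.
#' @param warn_extrapolation warn when inputs fall outside training ranges.
#' @param ... unused.
#' @return numeric vector of predictions in response units.
#' @export
predict.elicit_mlp <- function(object, newdata, warn_extrapolation = TRUE, ...) {
  x <- as.data.frame(newdata)
  missing_cols <- setdiff(object$input_names, names(x))
  if (length(missing_cols))
    stopf("newdata is missing input column(s): %s",
          paste(missing_cols, collapse = ", "))
  x <- as.matrix(x[object$input_names])
  storage.mode(x) <- "double"
  rng <- object$input_scaler
  if (warn_extrapolation) {
    out_of_range <- any(t(x) < rng[1, ] - 1e-9) || any(t(x) > rng[2, ] + 1e-9)
    if (out_of_range)
      warning("inputs outside the training range; predictions are extrapolations",
              call. = FALSE)
  }
  Xs <- sapply(seq_len(ncol(x)), function(j) scale_minmax(x[, j], rng[, j]))
  Xs <- matrix(Xs, nrow(x), ncol(x))
  w <- list(W1 = object$hidden_weights, b1 = object$hidden_biases,
            w2 = object$output_weights, b2 = object$output_bias)
  unscale_minmax(mlp_forward_scaled(w, Xs), object$target_scaler)
}

#' Evaluate a fitted surrogate on a data subset
#'
#' Computes the package's three goodness-of-fit statistics for any model with
#' a `predict()` method (perceptron or regression fit).
#'
#' @param object a fitted `elicit_mlp` or `elicit_mlr`.
#' @param newdata data frame of inputs.
#' @param y observed response vector.
#' @return a [fit_metrics()] list.
#' @export
evaluate_fit <- function(object, newdata, y) {
  pred <- if (inherits(object, "elicit_mlp"))
    predict(object, newdata, warn_extrapolation = FALSE)
  else predict(object, newdata)
  fit_metrics(y, pred)
}

#' @export
print.elicit_mlp <- function(x, ...) {
  cat(sprintf("Perceptron surrogate: %d inputs -> %d tansig units -> linear output\n",
              length(x$input_names), x$n_hidden))
  cat("inputs:", paste(x$input_names, collapse = ", "), "\n")
  cat(sprintf("trained %d epochs (seed %s), final scaled MSE %.3g\n",
              x$training$epochs, x$training$seed, x$training$final_loss))
  invisible(x)
}

#' @export
summary.elicit_mlp <- function(object, ...) {
  cat0 <- function(...) cat(sprintf(...))
  print(object)
  cat0("weights: hidden %dx%d + %d biases, output %d + 1 bias\n",
       nrow(object$hidden_weights), ncol(object$hidden_weights),
       length(object$hidden_biases), length(object$output_weights))
  if (!is.na(object$training$val_loss))
    cat0("best validation scaled MSE: %.3g (%d rows held out)\n",
         object$training$val_loss, object$training$n_val)
  invisible(object)
}

#' Residuals of a perceptron on supplied data
#' @param object an `elicit_mlp` model.
#' @param newdata inputs; `y` observed responses.
#' @param y observed response vector.
#' @param ... unused.
#' @export
residuals.elicit_mlp <- function(object, newdata, y, ...) {
  y - predict(object, newdata, warn_extrapolation = FALSE)
}

#' Training-error trace of a perceptron
#'
#' @param x an `elicit_mlp` model.
#' @param ... passed to [plot()].
#' @export
plot.elicit_mlp <- function(x, ...) {
  h <- x$training$loss_history
  plot(seq_along(h), h, type = "l", log = "y",
       xlab = "epoch", ylab = "batch MSE (scaled targets)",
       main = "perceptron training error", ...)
  invisible(x)
}
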