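# Shared fixtures built in code at test time.

# Fast training settings for tests that only need a decent (not polished) fit.
fast_control <- function(max_epochs = 3000, patience = 300)
  mlp_control(max_epochs = max_epochs, patience = patience)

# A small, quick GA configuration.
small_ga <- function(seed, generations = 120, population_size = 30)
  ga_config(population_size = population_size, generations = generations,
            seed = seed)

# Additive test response with well-separated input importances:
# x1 strongest, then x2, x3, x4. Returns list(x, y, order).
importance_data <- function(n = 200, noise = 0.1, seed = 1) {
  set.seed(seed)
  x <- as.data.frame(matrix(runif(n * 4, -1, 1), n, 4))
  names(x) <- c("x1", "x2", "x3", "x4")
  y <- 4 * x$x1 + 2.2 * x$x2 + 1.1 * x$x3 + 0.45 * x$x4 +
    rnorm(n, 0, noise)
  list(x = x, y = y, order = c("x1", "x2", "x3", "x4"))
}

# A tiny hand-built perceptron whose scalers are the identity on [-1, 1],
# so scaled and unscaled quantities coincide.
identity_mlp <- function(W1, b1, w2, b2, input_names = paste0("x", seq_len(ncol(W1)))) {
  structure(list(
    n_hidden = nrow(W1),
    input_names = input_names,
    input_scaler = rbind(rep(-1, ncol(W1)), rep(1, ncol(W1))),
    target_scaler = c(-1, 1),
    hidden_weights = W1, hidden_biases = b1,
    output_weights = w2, output_bias = b2,
    activation = c(hidden = "tansig", output = "purelin"),
    training = list(epochs = 0L, seed = NA_integer_, final_loss = NA_real_,
                    val_loss = NA_real_, loss_history = numeric(), n_val = 0L)
  ), class = "elicit_mlp")
}

# Brute-force OLS oracle: solve the normal equations directly.
ols_oracle <- function(x, y) {
  X <- cbind(1, as.matrix(x))
  solve(crossprod(X), crossprod(X, y))[, 1]
}
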