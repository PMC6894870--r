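# Thin R wrapper around the compiled fully-connected network trainer.
# Weight matrices have shape (out x in); layer l computes
# x_l = act_l(W_l x_{l-1} + b_l).

.ACT_CODES <- c(linear = 0L, relu = 1L, tanh = 2L, sigmoid = 3L)

.act_codes <- function(activations) {
  bad <- setdiff(activations, names(.ACT_CODES))
  if (length(bad)) stopf("unknown activation(s): %s", paste(bad, collapse = ", "))
  unname(.ACT_CODES[activations])
}

# Glorot-uniform initial weights, drawn with R's RNG so the fit is seeded
.init_layers <- function(widths) {
  L <- length(widths) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- widths[l]; fan_out <- widths[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    W[[l]] <- matrix(runif(fan_out * fan_in, -lim, lim), fan_out, fan_in)
    b[[l]] <- numeric(fan_out)
  }
  list(weights = W, biases = b)
}

# Fit a multilayer perceptron by minibatch Adamax.
# X: n x d inputs; Y: n x k targets; widths: c(d, hidden..., k);
# activations: one of "linear","relu","tanh","sigmoid" per affine layer.
mlp_fit <- function(X, Y, widths, activations,
                    loss = c("mse", "cross_entropy"),
                    learning_rate = 0.001, epochs = 200L, batch_size = 32L,
                    seed = 1L, shuffle = TRUE) {
  loss <- match.arg(loss)
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (ncol(X) != widths[1])
    stopf("input width %d does not match first layer width %d",
          ncol(X), widths[1])
  if (ncol(Y) != widths[length(widths)])
    stopf("target width %d does not match output layer width %d",
          ncol(Y), widths[length(widths)])
  if (length(activations) != length(widths) - 1L)
    stopf("need one activation per affine layer")
  fit <- with_seed(seed, {
    init <- .init_layers(widths)
    mlp_train_cpp(X, Y, init$weights, init$biases, .act_codes(activations),
                  if (loss == "cross_entropy") 1L else 0L,
                  learning_rate, as.integer(epochs), as.integer(batch_size),
                  shuffle)
  })
  structure(list(weights = fit$weights, biases = fit$biases,
                 widths = widths, activations = activations, loss = loss,
                 epoch_loss = fit$epoch_loss, seed = seed),
            class = "mlp")
}

mlp_predict <- function(object, X) {
  X <- as.matrix(X)
  if (ncol(X) != object$widths[1])
    stopf("input has %d columns; the network expects %d",
          ncol(X), object$widths[1])
  mlp_forward_cpp(X, object$weights, object$biases,
                  .act_codes(object$activations))
}
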