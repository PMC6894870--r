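# Reconstruction backends and reconstruction-error (RE) machinery: the deep
# autoencoder and the PCA back-projection alternative, per-sample RE, the
# RE feature extracted from a risky-subset model, the mean-plus-dispersion
# threshold and RE-based partitioning.

#' Deep autoencoder specification
#'
#' Six affine layers: a rectifier (relu) encoder of three layers and a
#' hyperbolic-tangent decoder of three layers, the output layer included.
#' Defaults follow the published training recipe (Adamax, learning rate
#' 0.001, batch size 32); hidden widths taper symmetrically to a bottleneck
#' of 4, mirroring the classifier's tapering widths, since only depth and
#' activations are fixed by the architecture. `epochs` defaults to the
#' desk-scale profile of 200; the full-scale 5000 is a plain argument.
#'
#' @param d Input (and output) width.
#' @param hidden The five hidden widths (3 encoder, 2 decoder).
#' @param learning_rate,epochs,batch_size Adamax minibatch settings.
#' @param linear_output Replace the output tanh by a linear layer
#'   (off by default: the stated stack ends in tanh even though z-scores can
#'   exceed \[-1, 1\]).
#' @param seed Integer seed.
#' @return An `ae_spec`.
#' @export
ae_spec <- function(d = 14L, hidden = c(10L, 7L, 4L, 7L, 10L),
                    learning_rate = 0.001, epochs = 200L, batch_size = 32L,
                    linear_output = FALSE, seed = 1L) {
  if (length(hidden) != 5L) stopf("need 5 hidden widths (6 affine layers)")
  widths <- c(d, hidden, d)
  if (any(widths <= 0)) stopf("layer widths must be positive")
  if (hidden[3] >= d) stopf("bottleneck width must be < input width %d", d)
  activations <- c("relu", "relu", "relu", "tanh", "tanh",
                   if (linear_output) "linear" else "tanh")
  structure(list(layer_widths = widths, activations = activations,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "ae_spec")
}

#' Fit the deep autoencoder backend
#'
#' Trains the 6-layer autoencoder on a standardized feature matrix by
#' minibatch Adamax minimising mean squared reconstruction error; the
#' per-epoch training loss is recorded. Reproducible from `spec$seed`.
#'
#' @param X Standardized numeric matrix (n x d).
#' @param spec An [ae_spec()] with matching `d`.
#' @param fitted_on Provenance tag: `"general"` (fit on all rows) or
#'   `"risky"` (fit on high-risk rows only).
#' @return A `recon_backend` of kind `"autoencoder"`.
#' @export
fit_autoencoder <- function(X, spec, fitted_on = c("general", "risky")) {
  fitted_on <- match.arg(fitted_on)
  stopifnot(inherits(spec, "ae_spec"))
  model <- mlp_fit(X, X, spec$layer_widths, spec$activations, loss = "mse",
                   learning_rate = spec$learning_rate, epochs = spec$epochs,
                   batch_size = spec$batch_size, seed = spec$seed)
  structure(list(kind = "autoencoder", model = model, d = ncol(X),
                 fitted_on = fitted_on, epoch_loss = model$epoch_loss),
            class = "recon_backend")
}

#' Fit the PCA reconstruction backend
#'
#' Stores the column means and the loadings of the leading principal
#' components; reconstruction projects onto the component span and back.
#'
#' @param X Standardized numeric matrix.
#' @param n_components Number of components, in 1..d.
#' @inheritParams fit_autoencoder
#' @return A `recon_backend` of kind `"pca"`.
#' @export
fit_pca_backend <- function(X, n_components,
                            fitted_on = c("general", "risky")) {
  fitted_on <- match.arg(fitted_on)
  X <- as.matrix(X)
  if (n_components < 1 || n_components > ncol(X))
    stopf("n_components must lie in 1..%d", ncol(X))
  center <- colMeans(X)
  V <- svd(sweep(X, 2, center), nu = 0)$v[, seq_len(n_components), drop = FALSE]
  structure(list(kind = "pca", center = center, loadings = V, d = ncol(X),
                 fitted_on = fitted_on), class = "recon_backend")
}

#' Reconstruct samples through a fitted backend
#'
#' @param backend A `recon_backend`.
#' @param X Matrix with width matching the backend.
#' @return Matrix of reconstructions, same shape as `X`.
#' @export
reconstruct <- function(backend, X) {
  X <- as.matrix(X)
  if (ncol(X) != backend$d)
    stopf("input width %d does not match backend width %d", ncol(X), backend$d)
  if (backend$kind == "autoencoder") {
    mlp_predict(backend$model, X)
  } else {
    Xc <- sweep(X, 2, backend$center)
    sweep(Xc %*% backend$loadings %*% t(backend$loadings), 2,
          backend$center, "+")
  }
}

#' Per-sample reconstruction error
#'
#' `re_i = mean_j (x_ij - xhat_ij)^2`: the per-row mean of squared
#' coordinate-wise reconstruction differences, a single nonnegative scalar
#' per sample.
#'
#' @inheritParams reconstruct
#' @return Nonnegative numeric vector of length `nrow(X)`.
#' @export
per_sample_re <- function(backend, X) {
  X <- as.matrix(X)
  rowMeans((X - reconstruct(backend, X))^2)
}

#' Extract the risky-subset RE feature
#'
#' Fits an autoencoder on the high-risk training rows only, then scores any
#' matrix by per-sample RE on that model. Rows resembling the high-risk
#' population reconstruct well (low RE); rows unlike it reconstruct poorly,
#' so the RE carries class information usable as an additional classifier
#' input.
#'
#' @param train_X Standardized training matrix.
#' @param labels 0/1 labels aligned with `train_X` rows.
#' @param spec An [ae_spec()].
#' @param score_on Matrix to score (defaults to `train_X`).
#' @return List with `re` (REVector on `score_on`) and `backend` (the fitted
#'   risky backend, for reuse at prediction time).
#' @export
extract_re_feature <- function(train_X, labels, spec, score_on = train_X) {
  risky <- as.matrix(train_X)[labels == 1, , drop = FALSE]
  if (nrow(risky) == 0) stopf("no high-risk rows to fit the risky model on")
  backend <- fit_autoencoder(risky, spec, fitted_on = "risky")
  list(re = per_sample_re(backend, score_on), backend = backend)
}

#' RE partition threshold
#'
#' `threshold = mean(re) + dispersion(re)` with the population (1/n)
#' convention. The default dispersion is the standard deviation (the stated
#' intent of the construction); the literal variance reading is selectable.
#'
#' @param re Nonnegative RE vector.
#' @param convention `"standard_deviation"` (default) or `"variance"`.
#' @return An `re_threshold` with `$value`, `$convention`, `$mean`.
#' @export
compute_threshold <- function(re,
                              convention = c("standard_deviation", "variance")) {
  convention <- match.arg(convention)
  if (length(re) == 0) stopf("cannot compute a threshold from an empty RE vector")
  m <- mean(re)
  v <- mean((re - m)^2)
  disp <- if (convention == "variance") v else sqrt(v)
  structure(list(value = m + disp, convention = convention, mean = m,
                 dispersion = disp), class = "re_threshold")
}

#' Partition rows by reconstruction error
#'
#' Rows whose RE strictly exceeds the threshold value form the high-RE
#' group; ties go to the low-RE group ("exceeds" is strict).
#'
#' @param re RE vector.
#' @param threshold An `re_threshold` (or single number).
#' @return List with integer index vectors `$high_idx` and `$low_idx`
#'   forming a disjoint cover of `seq_along(re)`.
#' @export
partition_by_re <- function(re, threshold) {
  value <- if (inherits(threshold, "re_threshold")) threshold$value
           else as.numeric(threshold)
  high <- which(re > value)
  list(high_idx = high, low_idx = setdiff(seq_along(re), high))
}
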