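# The routed dual-DNN risk model: a 15-input DNN classifier (14 risk
# factors + risky-model RE feature), two of which are trained on the
# high-RE / low-RE partitions of the training set and selected at
# prediction time by comparing the general-model RE to the threshold.

#' DNN classifier specification
#'
#' Four rectifier hidden layers of widths 10, 7, 5, 3 and a logistic-sigmoid
#' output neuron. The default loss is mean squared error on the sigmoid
#' output, matching the published training recipe (cross-entropy is
#' available); optimisation is minibatch Adamax at rate 0.001, batch 32.
#' `epochs` defaults to the desk-scale profile of 200 (full scale: 5000).
#'
#' @param input_width Input width (15 with the RE feature, 14 without).
#' @param hidden Hidden layer widths.
#' @param loss `"mse"` or `"cross_entropy"`.
#' @param learning_rate,epochs,batch_size Adamax minibatch settings.
#' @param decision_cutoff Probability cutoff for the hard label
#'   (label 1 iff probability >= cutoff).
#' @param seed Integer seed.
#' @return A `dnn_spec`.
#' @export
dnn_spec <- function(input_width = 15L, hidden = c(10L, 7L, 5L, 3L),
                     loss = c("mse", "cross_entropy"),
                     learning_rate = 0.001, epochs = 200L, batch_size = 32L,
                     decision_cutoff = 0.5, seed = 1L) {
  loss <- match.arg(loss)
  widths <- c(input_width, hidden, 1L)
  if (any(widths <= 0)) stopf("layer widths must be positive")
  if (decision_cutoff <= 0 || decision_cutoff >= 1)
    stopf("decision_cutoff must lie in (0, 1)")
  structure(list(layer_widths = widths,
                 activations = c(rep("relu", length(hidden)), "sigmoid"),
                 loss = loss, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 decision_cutoff = decision_cutoff, seed = as.integer(seed)),
            class = "dnn_spec")
}

#' Fit a DNN classifier
#'
#' @param X Standardized matrix whose width matches `spec`.
#' @param y 0/1 labels.
#' @param spec A [dnn_spec()].
#' @return A `dnn_model`.
#' @export
fit_dnn <- function(X, y, spec) {
  stopifnot(inherits(spec, "dnn_spec"))
  if (!is_binary(y)) stopf("labels must be 0/1")
  if (length(unique(y)) < 2)
    warning("training labels contain a single class; the fitted model will tend to a constant probability",
            call. = FALSE)
  model <- mlp_fit(X, matrix(as.numeric(y), ncol = 1), spec$layer_widths,
                   spec$activations, loss = spec$loss,
                   learning_rate = spec$learning_rate, epochs = spec$epochs,
                   batch_size = spec$batch_size, seed = spec$seed)
  structure(list(model = model, spec = spec), class = "dnn_model")
}

#' @describeIn fit_dnn Predicted probabilities (`type = "prob"`, default) or
#'   hard labels at the spec's decision cutoff (`type = "label"`).
#' @param object A `dnn_model`.
#' @param newdata Matrix with the model's input width.
#' @param type `"prob"` or `"label"`.
#' @param ... Unused.
#' @export
predict.dnn_model <- function(object, newdata, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  p <- as.vector(mlp_predict(object$model, newdata))
  if (type == "label") as.integer(p >= object$spec$decision_cutoff) else p
}

#' Fit the full routed dual-DNN classifier
#'
#' Training pipeline, in order: encode the 14 features and fit a 14-column
#' standardizer; fit the general reconstruction backend on all standardized
#' training rows; compute per-row RE and the mean-plus-dispersion threshold;
#' fit the risky backend on the high-risk (label 1) rows; score every
#' training row on the risky backend to obtain the RE feature; append it and
#' fit a fresh 15-column standardizer (the RE feature is standardized
#' jointly, otherwise its scale would be washed out next to z-scores);
#' partition rows by the general-backend RE threshold; train one DNN on the
#' high-RE group and one on the low-RE group. Every stochastic stage
#' consumes a sub-seed derived from `seed`, so the whole fit is reproducible.
#'
#' @param train A `cohort_table` containing both classes.
#' @param ae_specification An [ae_spec()] used for both backends when
#'   `backend = "autoencoder"`.
#' @param dnn_specification A [dnn_spec()]; both DNNs share it.
#' @param threshold_convention Passed to [compute_threshold()].
#' @param backend `"autoencoder"` (default) or `"pca"` — the PCA variant
#'   swaps only the reconstruction backend, all else identical.
#' @param n_components Components for the PCA backend.
#' @param re_feature Append the risky-model RE feature (default TRUE; FALSE
#'   gives the routed two-DNN model on the bare 14 features, used by the
#'   ablation ladder).
#' @param threshold_value Optional override of the computed threshold value
#'   (diagnostic hook; e.g. `Inf` forces everything into the low-RE group,
#'   which triggers the empty-group error).
#' @param seed Master seed.
#' @return An `ae_dnns` routed classifier bundle.
#' @export
fit_ae_dnns <- function(train, ae_specification = ae_spec(),
                        dnn_specification = dnn_spec(),
                        threshold_convention = c("standard_deviation",
                                                 "variance"),
                        backend = c("autoencoder", "pca"), n_components = 4L,
                        re_feature = TRUE, threshold_value = NULL,
                        seed = 1L) {
  threshold_convention <- match.arg(threshold_convention)
  backend <- match.arg(backend)
  train <- as_cohort_table(as.data.frame(train))
  y <- train$label
  if (length(unique(y)) < 2) stopf("training data must contain both classes")
  seeds <- derive_seeds(seed, 4L)

  X14 <- encode_features(train)
  std14 <- fit_standardizer(X14)
  Z14 <- apply_standardizer(std14, X14)

  fit_backend <- function(X, sub_seed, fitted_on) {
    if (backend == "autoencoder") {
      sp <- ae_specification; sp$seed <- sub_seed
      fit_autoencoder(X, sp, fitted_on = fitted_on)
    } else fit_pca_backend(X, n_components, fitted_on = fitted_on)
  }

  general <- fit_backend(Z14, seeds[1], "general")
  re_general <- per_sample_re(general, Z14)
  threshold <- compute_threshold(re_general, threshold_convention)
  if (!is.null(threshold_value)) threshold$value <- threshold_value

  risky_rows <- Z14[y == 1, , drop = FALSE]
  if (nrow(risky_rows) == 0) stopf("no high-risk rows to fit the risky backend")
  risky <- fit_backend(risky_rows, seeds[2], "risky")

  if (re_feature) {
    re_feat <- per_sample_re(risky, Z14)
    X15 <- cbind(X14, re_feature = re_feat)
  } else {
    X15 <- X14
  }
  std15 <- fit_standardizer(X15)
  Z15 <- apply_standardizer(std15, X15)

  part <- partition_by_re(re_general, threshold)
  for (side in c("high", "low")) {
    idx <- if (side == "high") part$high_idx else part$low_idx
    if (length(idx) == 0 || length(unique(y[idx])) < 2)
      stopf(paste("the %s-RE partition group lacks rows of both classes;",
                  "consider the other threshold convention"), side)
  }
  dsp <- dnn_specification
  dsp$layer_widths[1] <- ncol(Z15)
  dsp_high <- dsp; dsp_high$seed <- seeds[3]
  dsp_low <- dsp; dsp_low$seed <- seeds[4]
  dnn_high <- fit_dnn(Z15[part$high_idx, , drop = FALSE], y[part$high_idx],
                      dsp_high)
  dnn_low <- fit_dnn(Z15[part$low_idx, , drop = FALSE], y[part$low_idx],
                     dsp_low)

  structure(list(version = "1",
                 feature_order = cohort_feature_names(),
                 backend_kind = backend, n_components = n_components,
                 re_feature = re_feature,
                 standardizer14 = std14, standardizer15 = std15,
                 general_backend = general, threshold = threshold,
                 risky_backend = risky,
                 dnn_high = dnn_high, dnn_low = dnn_low,
                 threshold_convention = threshold_convention,
                 seed = as.integer(seed)),
            class = "ae_dnns")
}

#' Predict with a routed classifier
#'
#' Per row: standardize the 14 features; compute the general-backend RE;
#' route to the high-RE DNN when that RE strictly exceeds the threshold,
#' else to the low-RE DNN; compute the risky-backend RE feature; build the
#' standardized 15-vector and read the routed DNN's probability.
#'
#' @param object A fitted `ae_dnns` bundle.
#' @param newdata A `cohort_table` or data.frame with the 14 feature columns
#'   (any column order; columns are realigned by name).
#' @param ... Unused.
#' @return data.frame with `probability`, `label`, `route` ("high_re" /
#'   "low_re"), `re_general`, `re_feature` per row.
#' @export
predict.ae_dnns <- function(object, newdata, ...) {
  X14 <- encode_features(newdata)[, object$feature_order, drop = FALSE]
  Z14 <- apply_standardizer(object$standardizer14, X14)
  re_general <- per_sample_re(object$general_backend, Z14)
  re_feat <- per_sample_re(object$risky_backend, Z14)
  X15 <- if (object$re_feature) cbind(X14, re_feature = re_feat) else X14
  Z15 <- apply_standardizer(object$standardizer15, X15)
  high <- re_general > object$threshold$value
  p <- numeric(nrow(Z15))
  if (any(high))
    p[high] <- predict(object$dnn_high, Z15[high, , drop = FALSE])
  if (any(!high))
    p[!high] <- predict(object$dnn_low, Z15[!high, , drop = FALSE])
  cutoff <- object$dnn_high$spec$decision_cutoff
  data.frame(probability = p,
             label = as.integer(p >= cutoff),
             route = ifelse(high, "high_re", "low_re"),
             re_general = re_general,
             re_feature = re_feat,
             stringsAsFactors = FALSE)
}
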