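# Bundle serialization: a routed classifier round-trips through a single
# JSON text file. Numerics are written as "%.17g" strings, which round-trip
# IEEE doubles exactly, so a reloaded bundle predicts identically and two
# fits from the same master seed serialize to byte-identical files.

.ser_num <- function(v) as.list(num_to_chr(as.numeric(v)))

.ser_mat <- function(m) list(dim = as.list(dim(m)),
                             data = .ser_num(as.vector(m)))

.de_num <- function(x) chr_to_num(unlist(x))

.de_mat <- function(x) matrix(.de_num(x$data), nrow = x$dim[[1]],
                              ncol = x$dim[[2]])

.ser_mlp <- function(m) {
  list(widths = as.list(m$widths), activations = as.list(m$activations),
       loss = m$loss, weights = lapply(m$weights, .ser_mat),
       biases = lapply(m$biases, .ser_num))
}

.de_mlp <- function(x) {
  structure(list(weights = lapply(x$weights, .de_mat),
                 biases = lapply(x$biases, .de_num),
                 widths = as.integer(unlist(x$widths)),
                 activations = as.character(unlist(x$activations)),
                 loss = x$loss, epoch_loss = NULL, seed = NULL),
            class = "mlp")
}

.ser_backend <- function(b) {
  out <- list(kind = b$kind, fitted_on = b$fitted_on, d = b$d)
  if (b$kind == "autoencoder") out$model <- .ser_mlp(b$model)
  else { out$center <- .ser_num(b$center); out$loadings <- .ser_mat(b$loadings) }
  out
}

.de_backend <- function(x) {
  b <- list(kind = x$kind, fitted_on = x$fitted_on, d = as.integer(x$d))
  if (x$kind == "autoencoder") b$model <- .de_mlp(x$model)
  else { b$center <- .de_num(x$center); b$loadings <- .de_mat(x$loadings) }
  structure(b, class = "recon_backend")
}

.ser_dnn <- function(d) {
  sp <- d$spec
  list(model = .ser_mlp(d$model),
       spec = list(layer_widths = as.list(sp$layer_widths),
                   activations = as.list(sp$activations), loss = sp$loss,
                   learning_rate = num_to_chr(sp$learning_rate),
                   epochs = sp$epochs, batch_size = sp$batch_size,
                   decision_cutoff = num_to_chr(sp$decision_cutoff),
                   seed = sp$seed))
}

.de_dnn <- function(x) {
  sp <- x$spec
  spec <- structure(list(layer_widths = as.integer(unlist(sp$layer_widths)),
                         activations = as.character(unlist(sp$activations)),
                         loss = sp$loss,
                         learning_rate = chr_to_num(sp$learning_rate),
                         epochs = as.integer(sp$epochs),
                         batch_size = as.integer(sp$batch_size),
                         decision_cutoff = chr_to_num(sp$decision_cutoff),
                         seed = as.integer(sp$seed)), class = "dnn_spec")
  structure(list(model = .de_mlp(x$model), spec = spec), class = "dnn_model")
}

.ser_std <- function(s) list(mean = .ser_num(s$mean), sd = .ser_num(s$sd),
                             names = as.list(s$names))

.de_std <- function(x) {
  nm <- as.character(unlist(x$names))
  structure(list(mean = stats::setNames(.de_num(x$mean), nm),
                 sd = stats::setNames(.de_num(x$sd), nm), names = nm),
            class = "standardizer")
}

#' Save a routed classifier bundle
#'
#' Writes the complete fitted state (standardizers, both reconstruction
#' backends, threshold, both DNNs, feature order) to one JSON file with
#' full-precision numerics.
#'
#' @param clf A fitted `ae_dnns` bundle.
#' @param destination File path.
#' @return `destination`, invisibly.
#' @export
save_bundle <- function(clf, destination) {
  stopifnot(inherits(clf, "ae_dnns"))
  obj <- list(
    format = "aednns_bundle", version = clf$version,
    feature_order = as.list(clf$feature_order),
    backend_kind = clf$backend_kind, n_components = clf$n_components,
    re_feature = clf$re_feature,
    standardizer14 = .ser_std(clf$standardizer14),
    standardizer15 = .ser_std(clf$standardizer15),
    general_backend = .ser_backend(clf$general_backend),
    risky_backend = .ser_backend(clf$risky_backend),
    threshold = list(value = num_to_chr(clf$threshold$value),
                     convention = clf$threshold$convention,
                     mean = num_to_chr(clf$threshold$mean),
                     dispersion = num_to_chr(clf$threshold$dispersion)),
    dnn_high = .ser_dnn(clf$dnn_high), dnn_low = .ser_dnn(clf$dnn_low),
    threshold_convention = clf$threshold_convention, seed = clf$seed)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = FALSE),
             destination)
  invisible(destination)
}

#' Load a routed classifier bundle
#'
#' Fails with an explicit error (and no partial object) on truncated files
#' or schema/version mismatches.
#'
#' @param source Path written by [save_bundle()].
#' @return An `ae_dnns` bundle predicting identically to the saved one.
#' @export
load_bundle <- function(source) {
  obj <- tryCatch(jsonlite::fromJSON(source, simplifyVector = FALSE),
                  error = function(e)
                    stopf("cannot parse bundle file '%s': %s", source,
                          conditionMessage(e)))
  if (!identical(obj$format, "aednns_bundle"))
    stopf("'%s' is not a routed-classifier bundle", source)
  if (!identical(obj$version, "1"))
    stopf("unsupported bundle version '%s'", obj$version)
  structure(list(version = obj$version,
                 feature_order = as.character(unlist(obj$feature_order)),
                 backend_kind = obj$backend_kind,
                 n_components = as.integer(obj$n_components),
                 re_feature = isTRUE(obj$re_feature),
                 standardizer14 = .de_std(obj$standardizer14),
                 standardizer15 = .de_std(obj$standardizer15),
                 general_backend = .de_backend(obj$general_backend),
                 threshold = structure(
                   list(value = chr_to_num(obj$threshold$value),
                        convention = obj$threshold$convention,
                        mean = chr_to_num(obj$threshold$mean),
                        dispersion = chr_to_num(obj$threshold$dispersion)),
                   class = "re_threshold"),
                 risky_backend = .de_backend(obj$risky_backend),
                 dnn_high = .de_dnn(obj$dnn_high),
                 dnn_low = .de_dnn(obj$dnn_low),
                 threshold_convention = obj$threshold_convention,
                 seed = as.integer(obj$seed)),
            class = "ae_dnns")
}
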