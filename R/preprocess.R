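# Preprocessing: label derivation, feature encoding, standardization and
# cross-validation fold planning.

#' Derive risk labels from disorder flags
#'
#' A row is labelled high risk (1) when at least one of the six disorder
#' flags is set.
#'
#' @param flags data.frame or matrix of 6 binary columns.
#' @return Integer 0/1 vector.
#' @export
derive_labels <- function(flags) {
  m <- as.matrix(flags)
  if (anyNA(m) || !is_binary(m))
    stopf("disorder flags must be 0/1 with no missing values")
  as.integer(rowSums(m) > 0)
}

#' Encode a cohort as a numeric feature matrix
#'
#' Continuous features pass through; categorical features enter as their
#' integer survey codes in a single numeric column each (the published
#' 15-neuron input layer implies one column per feature, so no one-hot
#' expansion). Columns are returned in the canonical
#' [cohort_feature_names()] order regardless of input column order.
#'
#' @param table A `cohort_table` (or data.frame with the 14 feature columns).
#' @return Numeric matrix, n x 14.
#' @export
encode_features <- function(table) {
  feats <- cohort_feature_names()
  missing_cols <- setdiff(feats, names(table))
  if (length(missing_cols))
    stopf("missing feature column(s): %s", paste(missing_cols, collapse = ", "))
  codes <- cohort_category_codes()
  for (f in names(codes)) {
    bad <- which(!(table[[f]] %in% codes[[f]]))
    if (length(bad))
      stopf("unknown category code '%s' in column '%s' (row %d)",
            table[[f]][bad[1]], f, bad[1])
  }
  X <- as.matrix(as.data.frame(lapply(table[feats], as.numeric)))
  colnames(X) <- feats
  X
}

#' Fit a column standardizer
#'
#' Per-column mean and population (divide-by-n) standard deviation.
#'
#' @param X Numeric matrix.
#' @return A `standardizer` with `$mean`, `$sd`, `$names`.
#' @export
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  if (any(sdv <= 0)) {
    bad <- colnames(X)[sdv <= 0]
    if (is.null(bad)) bad <- which(sdv <= 0)
    stopf("constant column(s) cannot be standardized: %s",
          paste(bad, collapse = ", "))
  }
  structure(list(mean = mu, sd = sdv, names = colnames(X)),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param params A `standardizer` from [fit_standardizer()].
#' @param X Numeric matrix with matching width.
#' @return Matrix of z-scores.
#' @export
apply_standardizer <- function(params, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$mean))
    stopf("matrix has %d columns but the standardizer was fit on %d",
          ncol(X), length(params$mean))
  sweep(sweep(X, 2, params$mean), 2, params$sd, "/")
}

#' Invert a standardization
#'
#' @inheritParams apply_standardizer
#' @return Matrix on the original scale.
#' @export
unapply_standardizer <- function(params, X) {
  sweep(sweep(as.matrix(X), 2, params$sd, "*"), 2, params$mean, "+")
}

#' Plan (stratified) cross-validation folds
#'
#' Partitions `1:n` into `k` folds whose sizes differ by at most one. With
#' `stratify_on`, members of each stratum are spread across folds so every
#' fold's class mix tracks the global mix; extra members rotate across folds
#' so overall fold sizes stay balanced.
#'
#' @param n Number of rows.
#' @param k Number of folds (>= 2).
#' @param stratify_on Optional vector (e.g. labels) to stratify on.
#' @param seed Integer seed.
#' @return A `fold_plan` with `$k` and `$assignments` (fold index 1..k per row).
#' @export
make_folds <- function(n, k, stratify_on = NULL, seed = 1L) {
  if (k < 2) stopf("k must be >= 2")
  if (k > n) stopf("k = %d exceeds n = %d", k, n)
  if (!is.null(stratify_on) && length(stratify_on) != n)
    stopf("stratify_on must have length n")
  assignments <- integer(n)
  with_seed(seed, {
    strata <- if (is.null(stratify_on)) list(seq_len(n))
              else split(seq_len(n), stratify_on)
    offset <- 0L
    for (s in strata) {
      s <- if (length(s) > 1) sample(s) else s
      assignments[s] <- ((offset + seq_along(s) - 1L) %% k) + 1L
      offset <- (offset + length(s)) %% k
    }
  })
  structure(list(k = as.integer(k), assignments = assignments),
            class = "fold_plan")
}
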