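# Feature importance by leave-one-feature-out retraining, and recursive
# elimination of the lowest-ranked features.

# mean held-out accuracy of make_trainer(features) over the folds in `use`
.cv_accuracy <- function(data, make_trainer, plan, seed, features,
                         use = seq_len(plan$k)) {
  trainer <- make_trainer(features)
  seeds <- derive_seeds(seed, plan$k)
  accs <- numeric(0)
  preds <- list()
  for (i in use) {
    test_idx <- which(plan$assignments == i)
    train_idx <- which(plan$assignments != i)
    model <- trainer$fit(data[train_idx, , drop = FALSE], seeds[i])
    p <- trainer$predict(model, data[test_idx, , drop = FALSE])
    y <- data$label[test_idx]
    accs <- c(accs, mean(as.integer(p >= 0.5) == y))
    preds[[length(preds) + 1L]] <- data.frame(fold = i, row = test_idx,
                                              y_true = y,
                                              y_pred = as.integer(p >= 0.5))
  }
  list(accuracy = mean(accs), predictions = do.call(rbind, preds))
}

#' Rank features by leave-one-out accuracy drop
#'
#' Trains a baseline on all features, then once per feature with that
#' feature removed; features are ranked by descending accuracy drop
#' (`delta = baseline - accuracy_without`), rank 1 being the most
#' influential. Each accuracy is a cross-validated mean under a fixed seed
#' (set `single_split = TRUE` to score on the first held-out fold only).
#' Ties break by canonical feature order.
#'
#' @param data A `cohort_table`.
#' @param make_trainer Function mapping a feature-name vector to a trainer
#'   (see [trainers]); e.g. `function(f) trainer_dnn(features = f)`.
#' @param k Number of folds.
#' @param seed Seed shared by the fold plan and every retraining.
#' @param features Features to rank (default: all 14).
#' @param single_split Score on one held-out fold instead of the CV mean.
#' @return A `ranking_table` data.frame with `feature, accuracy_without,
#'   delta_from_baseline, rank` and the baseline accuracy in attribute
#'   `"baseline_accuracy"`.
#' @export
rank_by_elimination <- function(data, make_trainer, k = 5L, seed = 1L,
                                features = cohort_feature_names(),
                                single_split = FALSE) {
  if (length(features) < 2) stopf("need at least 2 features to rank")
  data <- as_cohort_table(as.data.frame(data))
  plan <- make_folds(nrow(data), k, stratify_on = data$label, seed = seed)
  use <- if (single_split) 1L else seq_len(plan$k)
  baseline <- .cv_accuracy(data, make_trainer, plan, seed, features,
                           use)$accuracy
  acc_without <- vapply(features, function(f)
    .cv_accuracy(data, make_trainer, plan, seed, setdiff(features, f),
                 use)$accuracy, numeric(1))
  delta <- baseline - acc_without
  ord <- order(-delta, seq_along(features))
  rank <- integer(length(features)); rank[ord] <- seq_along(features)
  out <- data.frame(feature = features, accuracy_without = acc_without,
                    delta_from_baseline = delta, rank = rank,
                    row.names = NULL)
  attr(out, "baseline_accuracy") <- baseline
  class(out) <- c("ranking_table", "data.frame")
  out
}

#' Recursive feature elimination along a ranking
#'
#' Removes features cumulatively in ascending importance (the
#' lowest-ranked, i.e. largest rank number, first), retraining at each of
#' the `d - 1` steps until a single feature remains, and records the
#' cross-validated accuracy after each removal.
#'
#' @inheritParams rank_by_elimination
#' @param ranking A `ranking_table` from [rank_by_elimination()].
#' @return An `elimination_table` data.frame with `step, removed_feature,
#'   accuracy, delta_from_baseline` (delta relative to the ranking's
#'   baseline).
#' @export
recursive_elimination <- function(data, make_trainer, ranking, k = 5L,
                                  seed = 1L, single_split = FALSE) {
  stopifnot(inherits(ranking, "ranking_table"))
  d <- nrow(ranking)
  if (d < 2) stopf("need at least 2 ranked features")
  data <- as_cohort_table(as.data.frame(data))
  plan <- make_folds(nrow(data), k, stratify_on = data$label, seed = seed)
  use <- if (single_split) 1L else seq_len(plan$k)
  baseline <- attr(ranking, "baseline_accuracy")
  removal_order <- ranking$feature[order(-ranking$rank)]
  steps <- list(); step_preds <- list()
  for (j in seq_len(d - 1L)) {
    remaining <- setdiff(ranking$feature, removal_order[seq_len(j)])
    res <- .cv_accuracy(data, make_trainer, plan, seed, remaining, use)
    steps[[j]] <- data.frame(step = j, removed_feature = removal_order[j],
                             accuracy = res$accuracy,
                             delta_from_baseline = baseline - res$accuracy)
    step_preds[[j]] <- res$predictions
  }
  out <- do.call(rbind, steps)
  rownames(out) <- NULL
  attr(out, "predictions") <- step_preds
  class(out) <- c("elimination_table", "data.frame")
  out
}
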