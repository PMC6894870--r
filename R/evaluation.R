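# Evaluation: confusion metrics, ROC/AUC with Hanley-McNeil inference,
# k-fold cross-validation of any fit/predict trainer, the comparator
# harness, and the three-step ablation ladder.

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Values in \[0, 1\].
#' @return The F-measure; `NA` when both inputs are 0.
#' @export
f_measure <- function(precision, recall) {
  ifelse(precision + recall == 0, NA_real_,
         2 * precision * recall / (precision + recall))
}

#' Confusion-matrix metrics
#'
#' Positive class is high risk (1). Ratios with a zero denominator are
#' reported as `NA` (a flagged null), never silently as 0.
#'
#' @param y_true,y_pred Binary vectors of equal length.
#' @return A `metrics_report` list: `tp fp fn tn accuracy precision recall
#'   specificity f_measure`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stopf("y_true and y_pred differ in length (%d vs %d)",
          length(y_true), length(y_pred))
  if (!is_binary(y_true) || !is_binary(y_pred))
    stopf("labels must be 0/1")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / length(y_true),
                 precision = precision, recall = recall,
                 specificity = ratio(tn, tn + fp),
                 f_measure = f_measure(precision, recall)),
            class = "metrics_report")
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney pair-win fraction — the probability that a random
#' positive outscores a random negative, ties counted one half — computed by
#' the rank formula. Curve points are monotone nondecreasing in both axes
#' and run from (0,0) to (1,1).
#'
#' @param scores Real-valued scores (higher = more positive).
#' @param y_true Binary labels with both classes present.
#' @return List with `auc` and `curve` (data.frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, y_true) {
  if (length(scores) != length(y_true)) stopf("scores and labels differ in length")
  if (!is_binary(y_true)) stopf("labels must be 0/1")
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0)
    stopf("both classes must be present to compute an ROC curve")
  r <- rank(scores)
  auc <- (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  tps <- cumsum(y_true[ord] == 1)
  fps <- cumsum(y_true[ord] == 0)
  last <- c(diff(scores[ord]) != 0, TRUE)   # one point per distinct score
  list(auc = auc,
       curve = data.frame(fpr = c(0, fps[last] / n_neg),
                          tpr = c(0, tps[last] / n_pos)))
}

#' Hanley-McNeil AUC inference
#'
#' Closed-form standard error of an AUC estimate:
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`,
#' `se = sqrt((A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) /
#' (n_pos n_neg))`, with `z = (A - 0.5)/se` tested two-sided against the
#' no-discrimination null and a 95% CI `A +/- 1.96 se` clipped to \[0, 1\].
#' For degenerate A in \{0, 1\} the formula gives `se = 0`; `z` is then
#' signed infinity and `p = 0`.
#'
#' @param auc AUC estimate in \[0, 1\].
#' @param n_pos,n_neg Class sizes (>= 1).
#' @return An `auc_report`: `auc se z p_value ci95`.
#' @export
hanley_mcneil <- function(auc, n_pos, n_neg) {
  if (auc < 0 || auc > 1) stopf("auc must lie in [0, 1]")
  if (n_pos < 1 || n_neg < 1) stopf("class sizes must be >= 1")
  a <- auc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
              (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
  if (se == 0) {
    z <- if (a == 0.5) 0 else sign(a - 0.5) * Inf
    p <- if (a == 0.5) 1 else 0
  } else {
    z <- (a - 0.5) / se
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc = a, se = se, z = z, p_value = p,
                 ci95 = c(max(0, a - 1.96 * se), min(1, a + 1.96 * se))),
            class = "auc_report")
}

# ---- trainers ---------------------------------------------------------------
# A trainer is a list(name, fit = function(train_table, seed) model,
# predict = function(model, table) probability vector). Comparators
# delegate to established implementations; the routed models wrap
# fit_ae_dnns.

.encode_subset <- function(table, features) {
  encode_features(table)[, features, drop = FALSE]
}

#' Trainer constructors for the evaluation harness
#'
#' Each constructor returns a `list(name, fit, predict)` usable with
#' [cross_validate()]: `fit(train_table, seed)` returns a fitted model and
#' `predict(model, table)` returns predicted probabilities of the high-risk
#' class. `trainer_ae_dnns()` / `trainer_pca_dnns()` wrap [fit_ae_dnns()]
#' (the PCA variant swaps only the reconstruction backend);
#' `trainer_dnn()` is a single DNN on the bare features; the remaining
#' constructors delegate to `e1071::naiveBayes`, `class::knn`,
#' `rpart::rpart`, `randomForest::randomForest` and `e1071::svm`, with the
#' published tuned settings as defaults (k = 19 neighbours, 110 trees, gini
#' splitting, radial kernel). All comparators operate on the standardized
#' encoded features restricted to `features`.
#'
#' @param ae_specification,dnn_specification,threshold_convention,n_components
#'   Passed to [fit_ae_dnns()].
#' @param re_feature Whether the routed model appends the RE feature.
#' @param features Feature subset (canonical names) the trainer uses.
#' @param k Neighbours for KNN.
#' @param split rpart splitting criterion, `"gini"` or `"information"`.
#' @param ntree Trees for the random forest.
#' @param kernel SVM kernel.
#' @name trainers
NULL

#' @rdname trainers
#' @export
trainer_ae_dnns <- function(ae_specification = ae_spec(),
                            dnn_specification = dnn_spec(),
                            threshold_convention = "standard_deviation",
                            re_feature = TRUE) {
  list(name = "ae_dnns",
       fit = function(train, seed)
         fit_ae_dnns(train, ae_specification, dnn_specification,
                     threshold_convention, backend = "autoencoder",
                     re_feature = re_feature, seed = seed),
       predict = function(model, table) predict(model, table)$probability)
}

#' @rdname trainers
#' @export
trainer_pca_dnns <- function(n_components = 4L,
                             dnn_specification = dnn_spec(),
                             threshold_convention = "standard_deviation",
                             re_feature = TRUE) {
  list(name = "pca_dnns",
       fit = function(train, seed)
         fit_ae_dnns(train, dnn_specification = dnn_specification,
                     threshold_convention = threshold_convention,
                     backend = "pca", n_components = n_components,
                     re_feature = re_feature, seed = seed),
       predict = function(model, table) predict(model, table)$probability)
}

#' @rdname trainers
#' @export
trainer_dnn <- function(dnn_specification = dnn_spec(),
                        features = cohort_feature_names()) {
  list(name = "dnn",
       fit = function(train, seed) {
         X <- .encode_subset(train, features)
         std <- fit_standardizer(X)
         sp <- dnn_specification
         sp$layer_widths[1] <- ncol(X)
         sp$seed <- seed
         list(std = std, dnn = fit_dnn(apply_standardizer(std, X),
                                       train$label, sp))
       },
       predict = function(model, table) {
         Z <- apply_standardizer(model$std, .encode_subset(table, features))
         predict(model$dnn, Z)
       })
}

.std_xy <- function(train, features) {
  X <- .encode_subset(train, features)
  std <- fit_standardizer(X)
  list(std = std, Z = apply_standardizer(std, X),
       y = factor(train$label, levels = c(0, 1)))
}

#' @rdname trainers
#' @export
trainer_nb <- function(features = cohort_feature_names()) {
  list(name = "nb",
       fit = function(train, seed) {
         d <- .std_xy(train, features)
         list(std = d$std, fit = e1071::naiveBayes(as.data.frame(d$Z), d$y))
       },
       predict = function(model, table) {
         Z <- apply_standardizer(model$std, .encode_subset(table, features))
         predict(model$fit, as.data.frame(Z), type = "raw")[, "1"]
       })
}

#' @rdname trainers
#' @export
trainer_knn <- function(k = 19L, features = cohort_feature_names()) {
  list(name = "knn",
       fit = function(train, seed) {
         d <- .std_xy(train, features)
         list(std = d$std, Z = d$Z, y = d$y, k = k, seed = seed)
       },
       predict = function(model, table) {
         Z <- apply_standardizer(model$std, .encode_subset(table, features))
         pred <- with_seed(model$seed,
                           class::knn(model$Z, Z, model$y, k = model$k,
                                      prob = TRUE))
         win <- attr(pred, "prob")
         ifelse(pred == "1", win, 1 - win)
       })
}

#' @rdname trainers
#' @export
trainer_dt <- function(split = c("gini", "information"),
                       features = cohort_feature_names()) {
  split <- match.arg(split)
  list(name = "dt",
       fit = function(train, seed) {
         d <- .std_xy(train, features)
         df <- data.frame(d$Z, .y = d$y, check.names = FALSE)
         list(std = d$std,
              fit = rpart::rpart(.y ~ ., df, method = "class",
                                 parms = list(split = split)))
       },
       predict = function(model, table) {
         Z <- apply_standardizer(model$std, .encode_subset(table, features))
         predict(model$fit, as.data.frame(Z), type = "prob")[, "1"]
       })
}

#' @rdname trainers
#' @export
trainer_rf <- function(ntree = 110L, features = cohort_feature_names()) {
  list(name = "rf",
       fit = function(train, seed) {
         d <- .std_xy(train, features)
         list(std = d$std,
              fit = with_seed(seed,
                              randomForest::randomForest(d$Z, d$y,
                                                         ntree = ntree)))
       },
       predict = function(model, table) {
         Z <- apply_standardizer(model$std, .encode_subset(table, features))
         predict(model$fit, Z, type = "prob")[, "1"]
       })
}

#' @rdname trainers
#' @export
trainer_svm <- function(kernel = "radial",
                        features = cohort_feature_names()) {
  list(name = "svm",
       fit = function(train, seed) {
         d <- .std_xy(train, features)
         list(std = d$std,
              fit = with_seed(seed,
                              e1071::svm(d$Z, d$y, kernel = kernel,
                                         probability = TRUE)))
       },
       predict = function(model, table) {
         Z <- apply_standardizer(model$std, .encode_subset(table, features))
         p <- predict(model$fit, Z, probability = TRUE)
         attr(p, "probabilities")[, "1"]
       })
}

.default_trainer <- function(method, ...) {
  switch(method,
         nb = trainer_nb(...), knn = trainer_knn(...), dt = trainer_dt(...),
         rf = trainer_rf(...), svm = trainer_svm(...),
         pca_dnns = trainer_pca_dnns(...), ae_dnns = trainer_ae_dnns(...),
         stopf("unknown method '%s'", method))
}

# ---- cross-validation -------------------------------------------------------

# vertical averaging of fold ROC curves on a fixed fpr grid
.mean_roc <- function(curves, grid = seq(0, 1, length.out = 101)) {
  tprs <- vapply(curves, function(cu)
    approx(cu$fpr, cu$tpr, xout = grid, ties = max, rule = 2)$y,
    numeric(length(grid)))
  m <- rowMeans(tprs)
  m[1] <- 0; m[length(m)] <- 1
  data.frame(fpr = grid, tpr = m)
}

.metrics_row <- function(m)
  data.frame(accuracy = m$accuracy, precision = m$precision,
             recall = m$recall, specificity = m$specificity,
             f_measure = m$f_measure)

#' k-fold cross-validation of a trainer
#'
#' For each fold, the trainer is fit on the remaining folds (all
#' preprocessing, reconstruction backends and thresholds refit inside the
#' trainer, so nothing leaks from the held-out fold) and scored on the held
#' fold. Reports per-fold confusion metrics and Hanley-McNeil AUC reports,
#' their means, pooled metrics over the concatenated held-out predictions,
#' per-fold ROC curves, the vertically averaged mean ROC, and the full
#' per-row prediction table.
#'
#' @param trainer A trainer (see [trainers]).
#' @param data A `cohort_table`.
#' @param folds A [make_folds()] plan matching `nrow(data)`.
#' @param seed Master seed; each fold's fit consumes a sub-seed.
#' @param cutoff Probability cutoff for hard labels.
#' @return A `cv_report`.
#' @export
cross_validate <- function(trainer, data, folds, seed = 1L, cutoff = 0.5) {
  data <- as_cohort_table(as.data.frame(data))
  stopifnot(inherits(folds, "fold_plan"),
            length(folds$assignments) == nrow(data))
  seeds <- derive_seeds(seed, folds$k)
  fold_metrics <- list(); fold_auc <- list(); curves <- list()
  preds <- list()
  for (i in seq_len(folds$k)) {
    test_idx <- which(folds$assignments == i)
    train_idx <- which(folds$assignments != i)
    y_train <- data$label[train_idx]
    if (length(unique(y_train)) < 2)
      stopf("fold %d leaves a single-class training set; use stratified folds",
            i)
    model <- trainer$fit(data[train_idx, , drop = FALSE], seeds[i])
    p <- trainer$predict(model, data[test_idx, , drop = FALSE])
    y <- data$label[test_idx]
    fold_metrics[[i]] <- confusion_metrics(y, as.integer(p >= cutoff))
    roc <- roc_auc(p, y)
    fold_auc[[i]] <- hanley_mcneil(roc$auc, sum(y == 1), sum(y == 0))
    curves[[i]] <- roc$curve
    preds[[i]] <- data.frame(fold = i, row = test_idx, y_true = y,
                             probability = p,
                             y_pred = as.integer(p >= cutoff))
  }
  preds <- do.call(rbind, preds)
  rownames(preds) <- NULL
  per_fold <- do.call(rbind, lapply(fold_metrics, .metrics_row))
  per_fold$auc <- vapply(fold_auc, `[[`, numeric(1), "auc")
  pooled <- confusion_metrics(preds$y_true, preds$y_pred)
  pooled_roc <- roc_auc(preds$probability, preds$y_true)
  structure(list(
    k = folds$k, trainer = trainer$name,
    per_fold = per_fold,
    fold_metrics = fold_metrics, fold_auc = fold_auc,
    fold_curves = curves, mean_roc = .mean_roc(curves),
    mean_metrics = colMeans(per_fold),
    pooled_metrics = pooled,
    pooled_auc = hanley_mcneil(pooled_roc$auc, sum(preds$y_true == 1),
                               sum(preds$y_true == 0)),
    predictions = preds), class = "cv_report")
}

#' Compare methods under a common fold plan
#'
#' One row per method with the cross-validated confusion metrics (fold
#' means), the mean fold AUC, and Hanley-McNeil significance of the pooled
#' AUC.
#'
#' @param data A `cohort_table`.
#' @param folds A [make_folds()] plan.
#' @param methods Character subset of `nb, knn, dt, rf, svm, pca_dnns,
#'   ae_dnns`, or a named list of trainer objects.
#' @param seed Master seed.
#' @return data.frame with columns `method, accuracy, precision, recall,
#'   specificity, f_measure, auc, p_value, ci_lower, ci_upper`, plus the
#'   underlying `cv_report`s in attribute `"reports"`.
#' @export
run_comparison <- function(data, folds, methods = c("nb", "rf", "ae_dnns"),
                           seed = 1L) {
  trainers <- if (is.list(methods)) methods
              else lapply(methods, .default_trainer)
  rows <- list(); reports <- list()
  for (tr in trainers) {
    rep <- cross_validate(tr, data, folds, seed = seed)
    mm <- rep$mean_metrics
    rows[[tr$name]] <- data.frame(
      method = tr$name, accuracy = mm[["accuracy"]],
      precision = mm[["precision"]], recall = mm[["recall"]],
      specificity = mm[["specificity"]], f_measure = mm[["f_measure"]],
      auc = mm[["auc"]], p_value = rep$pooled_auc$p_value,
      ci_lower = rep$pooled_auc$ci95[1], ci_upper = rep$pooled_auc$ci95[2])
    reports[[tr$name]] <- rep
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Ablation ladder: one DNN, two routed DNNs, two routed DNNs + RE feature
#'
#' Computes, for each seed, the mean cross-validated AUC of (a) a single
#' DNN on the 14 features, (b) the routed two-DNN model on the 14 features,
#' and (c) the full model with the RE feature appended, and reports the
#' mean over seeds for each rung.
#'
#' @param data A `cohort_table`.
#' @param k Folds per cross-validation.
#' @param seeds Integer vector of master seeds.
#' @param ae_specification,dnn_specification,threshold_convention Model
#'   settings shared by the rungs (the single DNN uses the dnn spec at
#'   width 14).
#' @return data.frame with `config` (`single_dnn`, `routed_dnns`,
#'   `routed_dnns_re`) and `mean_auc`, with the per-seed AUC matrix in
#'   attribute `"per_seed"`.
#' @export
ablation_auc <- function(data, k = 3L, seeds = 1:5,
                         ae_specification = ae_spec(),
                         dnn_specification = dnn_spec(),
                         threshold_convention = "standard_deviation") {
  data <- as_cohort_table(as.data.frame(data))
  configs <- list(
    single_dnn = trainer_dnn(dnn_specification),
    routed_dnns = trainer_ae_dnns(ae_specification, dnn_specification,
                                  threshold_convention, re_feature = FALSE),
    routed_dnns_re = trainer_ae_dnns(ae_specification, dnn_specification,
                                     threshold_convention, re_feature = TRUE))
  per_seed <- matrix(NA_real_, nrow = length(seeds), ncol = length(configs),
                     dimnames = list(NULL, names(configs)))
  for (s in seq_along(seeds)) {
    plan <- make_folds(nrow(data), k, stratify_on = data$label,
                       seed = seeds[s])
    for (cfg in names(configs)) {
      rep <- cross_validate(configs[[cfg]], data, plan, seed = seeds[s])
      per_seed[s, cfg] <- mean(rep$per_fold$auc)
    }
  }
  out <- data.frame(config = names(configs), mean_auc = colMeans(per_seed))
  rownames(out) <- NULL
  attr(out, "per_seed") <- per_seed
  out
}
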