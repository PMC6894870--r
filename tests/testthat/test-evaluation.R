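test_that("confusion metrics match hand computation and a brute recount", {
  # tp=3 fp=1 fn=1 tn=5
  y_true <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  y_pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  m <- confusion_metrics(y_true, y_pred)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$specificity, 5 / 6, tolerance = 1e-4)
  expect_equal(m$f_measure, 0.75)

  perfect <- confusion_metrics(c(0, 1, 1), c(0, 1, 1))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall",
                                   "specificity", "f_measure")]) == 1))
  # brute-force recount on random vectors
  set.seed(1)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    yt <- rbinom(n, 1, 0.5); yp <- rbinom(n, 1, 0.5)
    m <- confusion_metrics(yt, yp)
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (j in seq_len(n)) {
      if (yt[j] == 1 && yp[j] == 1) tp <- tp + 1
      if (yt[j] == 0 && yp[j] == 1) fp <- fp + 1
      if (yt[j] == 1 && yp[j] == 0) fn <- fn + 1
      if (yt[j] == 0 && yp[j] == 0) tn <- tn + 1
    }
    expect_equal(unlist(m[c("tp", "fp", "fn", "tn")]),
                 c(tp = tp, fp = fp, fn = fn, tn = tn))
  }
  # zero-denominator ratios are flagged nulls, not zeros
  m <- confusion_metrics(c(1, 1), c(0, 0))
  expect_true(is.na(m$precision))
  expect_error(confusion_metrics(c(0, 1), c(0)), "length")
})

test_that("AUC equals the Mann-Whitney pair-win fraction", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  # curve is monotone from (0,0) to (1,1)
  set.seed(2)
  s <- runif(50); y <- rbinom(50, 1, 0.5)
  cu <- roc_auc(s, y)$curve
  expect_equal(c(cu$fpr[1], cu$tpr[1]), c(0, 0))
  expect_equal(c(cu$fpr[nrow(cu)], cu$tpr[nrow(cu)]), c(1, 1))
  expect_true(all(diff(cu$fpr) >= 0) && all(diff(cu$tpr) >= 0))
  # independent cross-check against pROC
  skip_if_not_installed("pROC")
  expect_equal(roc_auc(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("Hanley-McNeil inference matches its closed form", {
  null <- hanley_mcneil(0.5, 20, 20)
  expect_equal(null$z, 0)
  expect_equal(null$p_value, 1)
  r <- hanley_mcneil(0.8, 50, 50)
  expect_equal(r$se, 0.0445, tolerance = 2e-3)
  expect_equal(r$z, 6.74, tolerance = 2e-3)
  expect_equal(r$ci95, c(0.8 - 1.96 * r$se, 0.8 + 1.96 * r$se))
  # se shrinks as 1/sqrt(n) at fixed AUC
  ses <- vapply(c(10, 50, 250, 1000),
                function(n) hanley_mcneil(0.8, n, n)$se, numeric(1))
  expect_true(all(diff(ses) < 0))
  # degenerate AUC of 1
  d <- hanley_mcneil(1, 10, 10)
  expect_equal(d$se, 0)
  expect_equal(d$p_value, 0)
})

test_that("cross-validation bookkeeping is exact", {
  tab <- small_cohort(n_low = 150, n_high = 100, seed = 20)
  folds <- make_folds(nrow(tab), 5, stratify_on = tab$label, seed = 1)
  rep <- cross_validate(constant_trainer(0.4), tab, folds)
  # constant classifier below cutoff predicts the negative class everywhere
  expect_equal(rep$pooled_metrics$accuracy, mean(tab$label == 0))
  expect_equal(nrow(rep$per_fold), 5)

  rep <- cross_validate(glm_trainer(), tab, folds)
  expect_true(all(rep$per_fold$auc > 0.5))
  # recompute per-fold metrics independently from the saved predictions
  for (i in 1:5) {
    pr <- rep$predictions[rep$predictions$fold == i, ]
    expect_equal(mean(pr$y_pred == pr$y_true), rep$per_fold$accuracy[i])
    expect_equal(roc_auc(pr$probability, pr$y_true)$auc,
                 rep$per_fold$auc[i])
  }
  # mean ROC endpoints and fold-curve monotonicity
  expect_equal(rep$mean_roc$tpr[1], 0)
  expect_equal(rep$mean_roc$tpr[nrow(rep$mean_roc)], 1)
  for (cu in rep$fold_curves)
    expect_true(all(diff(cu$fpr) >= 0) && all(diff(cu$tpr) >= 0))
})

test_that("a fold whose training set is single-class is rejected", {
  tab <- small_cohort(n_low = 19, n_high = 20, seed = 21)
  tab <- tab[order(-tab$label), ][c(1, 21:39), ]  # positive first, then 19 negatives
  folds <- make_folds(20, 2, seed = 1)
  folds$assignments <- rep(c(1L, 2L), 10)         # the only positive sits in fold 1
  expect_error(cross_validate(glm_trainer(), tab, folds), "single-class")
})

test_that("the comparator harness produces one row per method", {
  tab <- small_cohort(n_low = 120, n_high = 120, seed = 22)
  folds <- make_folds(nrow(tab), 3, stratify_on = tab$label, seed = 2)
  out <- run_comparison(tab, folds, methods = c("nb", "dt", "rf"), seed = 3)
  expect_equal(out$method, c("nb", "dt", "rf"))
  expect_named(out, c("method", "accuracy", "precision", "recall",
                      "specificity", "f_measure", "auc", "p_value",
                      "ci_lower", "ci_upper"))
  expect_true(all(out$auc > 0.5))
  single <- run_comparison(tab, folds, methods = "rf", seed = 3)
  expect_equal(nrow(single), 1)
  expect_error(run_comparison(tab, folds, methods = "boost"), "unknown method")
})

test_that("knn and svm comparators emit calibrated-range probabilities", {
  tab <- small_cohort(n_low = 100, n_high = 100, seed = 23)
  folds <- make_folds(nrow(tab), 2, stratify_on = tab$label, seed = 4)
  out <- run_comparison(tab, folds, methods = c("knn", "svm"), seed = 5)
  expect_true(all(out$accuracy > 0.5))
  reports <- attr(out, "reports")
  p <- reports$knn$predictions$probability
  expect_true(all(p >= 0 & p <= 1))
})

test_that("ablation ladder returns the three rungs in order", {
  tab <- small_cohort(n_low = 150, n_high = 150, seed = 24)
  out <- ablation_auc(tab, k = 2, seeds = 1,
                      ae_specification = tiny_ae(epochs = 20),
                      dnn_specification = tiny_dnn(epochs = 20))
  expect_equal(out$config, c("single_dnn", "routed_dnns", "routed_dnns_re"))
  expect_equal(nrow(out), 3)
  expect_true(all(out$mean_auc > 0.5))
})
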