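test_that("DNN classifier has the stated layer shapes", {
  set.seed(1)
  X <- matrix(rnorm(40 * 15), 40, 15)
  y <- rep(c(0, 1), 20)
  m <- fit_dnn(X, y, tiny_dnn(epochs = 2))
  expect_equal(lapply(m$model$weights, dim),
               list(c(10L, 15L), c(7L, 10L), c(5L, 7L), c(3L, 5L),
                    c(1L, 3L)))
  expect_equal(m$model$activations,
               c("relu", "relu", "relu", "relu", "sigmoid"))
})

test_that("DNN learns linearly separable data", {
  set.seed(2)
  n <- 500
  X <- rbind(matrix(rnorm(n * 15, -1, 1), n, 15),
             matrix(rnorm(n * 15, 1, 1), n, 15))
  y <- rep(c(0, 1), each = n)
  m <- fit_dnn(X, y, dnn_spec(epochs = 200, seed = 4))
  acc <- mean(predict(m, X, type = "label") == y)
  expect_gte(acc, 0.95)
  p <- predict(m, X)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("single-class labels warn and drive probabilities to the class", {
  set.seed(3)
  X <- matrix(rnorm(100 * 15), 100, 15)
  expect_warning(m <- fit_dnn(X, rep(0, 100), dnn_spec(epochs = 300, seed = 1)),
                 "single class")
  expect_true(all(predict(m, X) <= 0.1))
})

test_that("routed fit partitions the training set and both routes occur", {
  tab <- small_cohort(n_low = 250, n_high = 250, seed = 10)
  clf <- fit_ae_dnns(tab, tiny_ae(), tiny_dnn(), seed = 5)
  pr <- predict(clf, tab)
  expect_setequal(unique(pr$route), c("high_re", "low_re"))
  expect_equal(nrow(pr), nrow(tab))
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  expect_identical(pr$label, as.integer(pr$probability >= 0.5))
  expect_identical((pr$re_general > clf$threshold$value),
                   pr$route == "high_re")
})

test_that("an unreachable threshold triggers the empty-group error", {
  tab <- small_cohort(n_low = 100, n_high = 100, seed = 11)
  expect_error(fit_ae_dnns(tab, tiny_ae(), tiny_dnn(),
                           threshold_value = Inf, seed = 1),
               "high-RE partition group")
})

test_that("routed fits are deterministic end to end under a master seed", {
  tab <- small_cohort(n_low = 120, n_high = 120, seed = 12)
  clf1 <- fit_ae_dnns(tab, tiny_ae(epochs = 20), tiny_dnn(epochs = 20),
                      seed = 99)
  clf2 <- fit_ae_dnns(tab, tiny_ae(epochs = 20), tiny_dnn(epochs = 20),
                      seed = 99)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  save_bundle(clf1, f1); save_bundle(clf2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(predict(clf1, tab), predict(clf2, tab))
})

test_that("extreme rows reconstruct poorly and route to the high-RE model", {
  tab <- small_cohort(n_low = 200, n_high = 200, seed = 13)
  clf <- fit_ae_dnns(tab, tiny_ae(), tiny_dnn(), seed = 2)
  extreme <- as.data.frame(tab[1, ])
  for (f in c("age", "total_cholesterol", "neutral_fat", "systolic_bp"))
    extreme[[f]] <- max(tab[[f]]) * 10
  expect_identical(predict(clf, extreme)$route, "high_re")
  # a threshold above every test RE forces the low-RE route
  clf_low <- clf
  clf_low$threshold$value <- Inf
  expect_true(all(predict(clf_low, tab)$route == "low_re"))
})

test_that("bundles round-trip through JSON with identical predictions", {
  tab <- small_cohort(n_low = 120, n_high = 120, seed = 14)
  clf <- fit_ae_dnns(tab, tiny_ae(epochs = 15), tiny_dnn(epochs = 15),
                     seed = 7)
  f <- withr::local_tempfile(fileext = ".json")
  save_bundle(clf, f)
  back <- load_bundle(f)
  newdata <- small_cohort(n_low = 50, n_high = 50, seed = 15)
  p1 <- predict(clf, newdata); p2 <- predict(back, newdata)
  expect_equal(p1$probability, p2$probability, tolerance = 1e-12)
  expect_identical(p1$route, p2$route)
  # column-name realignment: permuted input columns give the same output
  perm <- newdata[, rev(names(newdata))]
  expect_equal(predict(back, perm)$probability, p2$probability,
               tolerance = 1e-12)
  # truncated bundle fails cleanly
  txt <- readLines(f)
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(txt, 1, nchar(txt) %/% 2), f2)
  expect_error(load_bundle(f2), "cannot parse")
})

test_that("the PCA backend variant swaps in without other changes", {
  tab <- small_cohort(n_low = 150, n_high = 150, seed = 16)
  clf <- fit_ae_dnns(tab, dnn_specification = tiny_dnn(), backend = "pca",
                     n_components = 4, seed = 3)
  expect_equal(clf$backend_kind, "pca")
  expect_equal(clf$general_backend$kind, "pca")
  pr <- predict(clf, tab)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
})
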