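test_that("autoencoder has six affine layers with the stated shapes", {
  set.seed(1)
  X <- matrix(rnorm(50 * 14), 50, 14)
  b <- fit_autoencoder(X, tiny_ae(epochs = 2))
  dims <- lapply(b$model$weights, dim)
  expect_equal(dims, list(c(10L, 14L), c(7L, 10L), c(4L, 7L), c(7L, 4L),
                          c(10L, 7L), c(14L, 10L)))
  expect_equal(b$model$activations,
               c("relu", "relu", "relu", "tanh", "tanh", "tanh"))
  expect_equal(ae_spec()$learning_rate, 0.001)
})

test_that("autoencoder training reduces the reconstruction loss", {
  set.seed(2)
  X <- scale(matrix(rnorm(500 * 14), 500, 14))
  b <- fit_autoencoder(X, tiny_ae(epochs = 200, seed = 3))
  expect_lte(b$epoch_loss[200], b$epoch_loss[1])
  # final-epoch training MSE equals the mean per-sample RE on that data
  expect_equal(mean(per_sample_re(b, X)), b$epoch_loss[200],
               tolerance = 1e-10)
})

test_that("PCA backend matches an eigen-decomposition oracle", {
  set.seed(3)
  X <- matrix(rnorm(20 * 5), 20, 5)
  # full rank: reconstruction is exact
  full <- fit_pca_backend(X, 5)
  expect_lt(max(per_sample_re(full, X)), 1e-12)
  # data exactly on a line: one component reconstructs it exactly
  line <- cbind(1:10, 2 * (1:10))
  expect_lt(max(per_sample_re(fit_pca_backend(line, 1), line)), 1e-12)
  # toy set: RE of (0,1) is its squared distance to the first principal
  # axis divided by d = 2, via an explicit eigen oracle
  toy <- rbind(c(1, 1), c(-1, -1), c(2, 2), c(-2, -2), c(0, 1))
  ctr <- colMeans(toy)
  ev <- eigen(cov(toy))$vectors[, 1]
  xc <- toy[5, ] - ctr
  dist2 <- sum((xc - ev * sum(xc * ev))^2)
  expect_equal(per_sample_re(fit_pca_backend(toy, 1), toy)[5], dist2 / 2,
               tolerance = 1e-8)
  # general random-case equivalence against the oracle
  for (i in 1:10) {
    n <- sample(5:20, 1); d <- sample(2:5, 1)
    k <- sample.int(d, 1)
    M <- matrix(rnorm(n * d), n, d)
    ctr <- colMeans(M)
    V <- eigen(crossprod(sweep(M, 2, ctr)))$vectors[, seq_len(k), drop = FALSE]
    Mc <- sweep(M, 2, ctr)
    oracle <- rowMeans((Mc - Mc %*% V %*% t(V))^2)
    expect_equal(per_sample_re(fit_pca_backend(M, k), M), oracle,
                 tolerance = 1e-8)
  }
  expect_error(fit_pca_backend(X, 6), "n_components")
})

test_that("per-sample RE is the coordinate mean of squared residuals", {
  # backend that reconstructs every row as its center (zero loadings)
  b <- structure(list(kind = "pca", center = c(0, 0, 1),
                      loadings = matrix(0, 3, 1), d = 3,
                      fitted_on = "general"), class = "recon_backend")
  expect_equal(per_sample_re(b, matrix(c(1, 0, 1), 1)), 1 / 3)
  # exact reconstruction gives zero
  X <- matrix(rnorm(30), 10, 3)
  expect_lt(max(per_sample_re(fit_pca_backend(X, 3), X)), 1e-12)
  # homogeneity: scaling residuals by c scales RE by c^2
  b0 <- structure(list(kind = "pca", center = c(0, 0, 0),
                       loadings = matrix(0, 3, 1), d = 3,
                       fitted_on = "general"), class = "recon_backend")
  expect_equal(per_sample_re(b0, 3 * X), 9 * per_sample_re(b0, X),
               tolerance = 1e-12)
  expect_error(per_sample_re(b0, matrix(0, 2, 4)), "width")
})

test_that("risky-subset RE feature separates unlike rows", {
  set.seed(5)
  risky <- matrix(rnorm(300 * 6, 0, 0.3), 300, 6)
  other <- matrix(rnorm(300 * 6, 0, 0.3), 300, 6) + 2
  X <- rbind(risky, other)
  y <- rep(c(1, 0), each = 300)
  sp <- ae_spec(d = 6, hidden = c(5, 4, 3, 4, 5), epochs = 150, seed = 11)
  res <- extract_re_feature(X, y, sp, score_on = X)
  expect_equal(res$backend$fitted_on, "risky")
  expect_lt(mean(res$re[y == 1]), mean(res$re[y == 0]))
  # determinism
  res2 <- extract_re_feature(X, y, sp, score_on = X)
  expect_identical(res$re, res2$re)
  expect_error(extract_re_feature(X, rep(0, 600), sp), "high-risk")
})

test_that("a single risky row is memorized to near-zero RE", {
  x <- matrix(seq(-0.5, 0.5, length.out = 14), 1, 14)
  sp <- ae_spec(epochs = 800, batch_size = 1, seed = 2)
  res <- extract_re_feature(x, 1, sp, score_on = x)
  expect_lt(res$re, 1e-3)
})

test_that("threshold is mean plus dispersion under both conventions", {
  expect_equal(compute_threshold(c(5, 5, 5))$value, 5)
  expect_equal(compute_threshold(c(1, 2, 3))$value, 2 + sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(compute_threshold(c(1, 2, 3), "variance")$value, 2 + 2 / 3,
               tolerance = 1e-12)
  expect_error(compute_threshold(numeric(0)), "empty")
  # dominance: threshold >= mean under both conventions
  set.seed(6)
  for (i in 1:25) {
    re <- rexp(sample(2:50, 1))
    expect_gte(compute_threshold(re)$value, mean(re))
    expect_gte(compute_threshold(re, "variance")$value, mean(re))
  }
})

test_that("partitioning is a strict-inequality disjoint cover", {
  expect_length(partition_by_re(c(1, 2, 3), 10)$high_idx, 0)
  p <- partition_by_re(c(1, 3, 5), 3)
  expect_identical(p$high_idx, 3L)
  expect_setequal(p$low_idx, c(1L, 2L))
  set.seed(7)
  for (i in 1:20) {
    re <- runif(sample(1:40, 1))
    th <- compute_threshold(re)
    p <- partition_by_re(re, th)
    expect_length(intersect(p$high_idx, p$low_idx), 0)
    expect_setequal(c(p$high_idx, p$low_idx), seq_along(re))
  }
})
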