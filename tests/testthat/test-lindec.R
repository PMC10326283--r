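test_that("z-scoring uses training statistics and handles constants", {
  set.seed(20)
  X <- cbind(rnorm(100, 5, 2), rnorm(100, -1, 0.5), rep(3, 100))
  st <- fit_zscore(X)
  Z <- apply_zscore(st, X)
  expect_true(all(abs(colMeans(Z)) < 1e-10))
  expect_true(all(abs(apply(Z[, 1:2], 2, sd) - 1) < 1e-10))
  expect_true(all(Z[, 3] == 0))            # constant column maps to zero
  expect_equal(st$sd[3], 1)
  # the state does not depend on test data
  st2 <- fit_zscore(X)
  expect_identical(st, st2)
  expect_equal(invert_zscore(st, Z), X, ignore_attr = TRUE)
})

test_that("PCA basis is orthonormal with non-increasing variances", {
  set.seed(21)
  X <- matrix(rnorm(200 * 10), 200, 10) %*% diag(10:1)
  pc <- fit_pca(X, 5)
  G <- crossprod(pc$rotation)
  expect_lt(max(abs(G - diag(5))), 1e-8)
  expect_true(all(diff(pc$explained) <= 1e-8))
  expect_error(fit_pca(X, 11), "exceeds")

  # rank-2 data reconstructs exactly from 2 components
  X2 <- matrix(rnorm(200 * 2), 200, 2) %*% matrix(rnorm(2 * 6), 2, 6)
  pc2 <- fit_pca(X2, 2)
  recon <- apply_pca(pc2, X2) %*% t(pc2$rotation)
  recon <- sweep(recon, 2, pc2$center, "+")
  expect_lt(max(abs(recon - X2)), 1e-8)
})

test_that("OLS matches the normal-equations oracle and recovers weights", {
  set.seed(22)
  X <- matrix(rnorm(300 * 8), 300, 8)
  W <- matrix(rnorm(8 * 3), 8, 3)
  Y <- X %*% W
  m <- fit_ols(X, Y)
  expect_lt(max(abs(m$weights - W)), 1e-8)

  Yn <- Y + matrix(rnorm(900, sd = 0.3), 300, 3)
  m2 <- fit_ols(X, Yn)
  oracle <- solve(crossprod(X), crossprod(X, Yn))
  expect_lt(max(abs(m2$weights - oracle)), 1e-8)

  # an all-zero output column gets an all-zero weight column
  m3 <- fit_ols(X, cbind(Yn, 0))
  expect_true(all(m3$weights[, 4] == 0))

  expect_warning(fit_ols(cbind(X, X[, 1]), Yn), "rank-deficient")
})

test_that("ridge shrinks monotonically and approaches OLS at small lambda", {
  set.seed(23)
  X <- scale(matrix(rnorm(400 * 6), 400, 6), scale = FALSE)
  Y <- X %*% matrix(rnorm(6 * 2), 6, 2) + matrix(rnorm(800, sd = 0.5), 400, 2)
  norms <- vapply(10^seq(-4, 4), function(l)
    sqrt(sum(fit_ridge(X, Y, "cv", lambda_grid = l)$weights^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  near0 <- fit_ridge(X, Y, "cv", lambda_grid = 1e-8)
  expect_lt(max(abs(near0$weights - fit_ols(X, Y)$weights)), 1e-4)
  expect_error(fit_ridge(X, Y, "cv", lambda_grid = numeric(0)), "empty")

  # solution path is continuous in lambda
  grid <- 10^seq(-2, 2, length.out = 9)
  Ws <- lapply(grid, function(l)
    fit_ridge(X, Y, "cv", lambda_grid = l)$weights)
  steps <- vapply(2:9, function(i) sqrt(sum((Ws[[i]] - Ws[[i - 1]])^2)),
                  numeric(1))
  expect_lt(max(steps), 0.5 * sqrt(sum(Ws[[1]]^2)))
})

test_that("per-output CV ridge penalizes the noisier output more", {
  hits <- 0
  for (rep in 1:50) {
    set.seed(300 + rep)
    X <- matrix(rnorm(150 * 10), 150, 10)
    W <- matrix(rnorm(10 * 2), 10, 2)
    Y <- X %*% W + cbind(rnorm(150, sd = 0.1), rnorm(150, sd = 10))
    m <- fit_ridge(X, Y, "cv_multi")
    if (m$hyper$lambda[2] > m$hyper$lambda[1]) hits <- hits + 1
  }
  expect_gte(hits, 45)   # >= 90% of runs
})

test_that("PLS with full rank matches OLS and finds single latent factors", {
  set.seed(24)
  X <- scale(matrix(rnorm(200 * 6), 200, 6), scale = FALSE)
  Y <- scale(X %*% matrix(rnorm(6 * 3), 6, 3) +
               matrix(rnorm(600, sd = 0.2), 200, 3), scale = FALSE)
  full <- fit_pls(X, Y, 6)
  ols <- fit_ols(X, Y)
  expect_lt(max(abs(X %*% full$weights - X %*% ols$weights)), 1e-6)

  # one latent direction of a whitened design: a single component captures
  # the response
  X <- qr.Q(qr(X)) * sqrt(nrow(X))
  t1 <- X %*% rnorm(6)
  Y1 <- scale(t1 %*% t(rnorm(3)), scale = FALSE)
  one <- fit_pls(X, Y1, 1)
  resid <- Y1 - X %*% one$weights
  expect_gt(1 - sum(resid^2) / sum(Y1^2), 0.99)

  # predictions are invariant to an orthogonal rotation of the outputs
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  rot <- fit_pls(X, Y %*% Q, 4)
  base <- fit_pls(X, Y, 4)
  expect_lt(max(abs((X %*% rot$weights) %*% t(Q) - X %*% base$weights)),
            1e-6)
  expect_error(fit_pls(X, Y, 0), "n_components")
})

test_that("the fit/predict pipeline respects the canonical step order", {
  set.seed(25)
  nsent <- 6
  neural <- lapply(1:nsent, function(i)
    feature_track(matrix(rnorm(80 * 5), 80, 5)))
  targets <- lapply(neural, function(x) {
    m <- unclass(x)
    feature_track(cbind(m[clamp_idx_test(seq_len(80) - 2, 80), 1] * 2 + 1,
                        m[, 2] - m[, 3]))
  })
  cfg <- windowing_config(50, 0)
  m <- train_decoder(neural[1:5], targets[1:5], "ols", cfg, n_pca = 5)
  pred <- predict(m, neural[[6]])
  r <- pearson_per_sentence(pred, targets[[6]])
  expect_gt(min(r), 0.95)

  # constant input at the training mean predicts the target training mean
  mu_x <- m$preproc$zx$mean
  const <- feature_track(matrix(mu_x, 40, 5, byrow = TRUE))
  p0 <- unclass(predict(m, const))
  mu_y <- colMeans(do.call(rbind, lapply(targets[1:5], unclass)))
  expect_lt(max(abs(sweep(p0, 2, mu_y))), 0.15)

  # PCA before context differs from PCA after context on a crafted case:
  # permuting the two steps changes the prediction
  delayed <- lapply(neural[1:5], function(x)
    apply_zscore(m$preproc$zx, feature_track(unclass(x))))
  alt_pca <- fit_pca(do.call(rbind, lapply(delayed, function(x)
    unclass(window_features(x, cfg)))), 5)
  x6 <- apply_zscore(m$preproc$zx, feature_track(unclass(neural[[6]])))
  ours <- unclass(window_features(apply_pca(m$preproc$pca, x6), cfg))
  theirs <- unclass(apply_pca(alt_pca, window_features(x6, cfg)))
  expect_false(ncol(ours) == ncol(theirs) &&
                 max(abs(ours - theirs)) < 1e-8)
})
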