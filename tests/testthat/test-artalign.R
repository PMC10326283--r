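test_that("midsagittal projection drops lip corners and keeps 14 features", {
  set.seed(11)
  n <- 200
  ema3d <- matrix(rnorm(n * 27), n, 27)
  out <- project_midsagittal(ema3d)
  expect_equal(ncol(out), 14)
  expect_error(project_midsagittal(ema3d[, 1:24]), "9 sensors")
})

test_that("projection keeps planar motion and loses only the third axis", {
  set.seed(12)
  n <- 300
  ema3d <- matrix(rnorm(n * 27), n, 27)
  # sensor 1 moves in a tilted plane: the two components keep all variance
  u <- cbind(rnorm(n), rnorm(n))
  basis <- qr.Q(qr(matrix(rnorm(9), 3, 3)))[, 1:2]
  ema3d[, 1:3] <- u %*% t(basis)
  out <- project_midsagittal(ema3d)
  cen <- scale(ema3d[, 1:3], scale = FALSE)
  expect_lt(abs(sum(out[, 1:2]^2) / sum(cen^2) - 1), 1e-10)

  # per-sensor reconstruction error equals the dropped third eigenvalue
  xyz <- ema3d[, 13:15]                       # sensor 5
  xyz <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(xyz) / (n - 1), symmetric = TRUE)$values
  kept <- out[, 5:6]                          # sensor 5 is 3rd kept sensor?
  # locate sensor 5 columns by label
  cols <- grep("^s5_", colnames(out))
  resid_var <- (sum(xyz^2) - sum(out[, cols]^2)) / (n - 1)
  expect_lt(abs(resid_var - ev[3]), 1e-8)
})

test_that("DTW feature vectors are normalized 27-dimensional tracks", {
  vowel <- make_test_vowel(150)
  speech <- rep(1, 150)
  f <- build_dtw_features(vowel$mel, vowel$f0, speech)
  expect_equal(ncol(f), 27)
  expect_equal(max(abs(unclass(f)[, 1])), 1)            # c0 normalized
  expect_equal(max(unclass(f)[, 26]), 1)                # F0 normalized

  # fully unvoiced: the F0 column stays all zero (no division by zero)
  f2 <- build_dtw_features(vowel$mel, rep(0, 150), speech)
  expect_true(all(unclass(f2)[, 26] == 0))
  expect_error(build_dtw_features(vowel$mel[0, , drop = FALSE], numeric(0),
                                  numeric(0)), "empty")
})

test_that("resample_to_length preserves endpoints, shape and monotonicity", {
  ramp <- feature_track(matrix(seq(0, 1, length.out = 50), ncol = 1))
  same <- resample_to_length(ramp, 50)
  expect_lt(max(abs(unclass(same) - unclass(ramp))), 1e-9)
  up <- resample_to_length(ramp, 101)
  expect_true(all(diff(unclass(up)[, 1]) > 0))           # pchip keeps monotone
  expect_equal(unclass(up)[c(1, 101), 1], c(0, 1))
  expect_error(resample_to_length(ramp, 1), ">= 2")

  # symmetric padding reduces edge overshoot on a step-like signal
  step <- c(rep(0, 10), rep(1, 10))
  padded <- unclass(resample_to_length(feature_track(step), 61))[, 1]
  unpadded <- pracma::pchip(seq_along(step), step,
                            seq(1, 20, length.out = 61))
  over <- function(v) max(max(v) - 1, -min(v), 0)
  expect_lte(over(padded), over(unpadded))
})

test_that("dtw_align matches the exhaustive dynamic-programming oracle", {
  set.seed(13)
  for (case in 1:60) {
    n <- sample(2:8, 1); m <- n; d <- sample(1:3, 1)
    A <- matrix(rnorm(n * d), n, d)
    B <- matrix(rnorm(m * d), m, d)
    wp <- dtw_align(A, B)
    D <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    expect_equal(attr(wp, "cost"), dtw_oracle_cost(D), tolerance = 1e-10)
    # path cost equals the claimed cost
    expect_equal(sum(D[wp]), attr(wp, "cost"), tolerance = 1e-10)
  }
})

test_that("dtw_align is boundary-anchored, monotone and symmetric", {
  set.seed(14)
  A <- matrix(rnorm(20 * 3), 20, 3)
  self <- dtw_align(A, A)
  expect_equal(unclass(self)[, 1], 1:20, ignore_attr = TRUE)
  expect_equal(attr(self, "cost"), 0, tolerance = 1e-12)

  B <- matrix(rnorm(20 * 3), 20, 3)
  ab <- dtw_align(A, B); ba <- dtw_align(B, A)
  expect_equal(attr(ab, "cost"), attr(ba, "cost"), tolerance = 1e-10)
  expect_error(dtw_align(A, B[1:10, ]), "same length")
})

test_that("transfer_articulation averages matched frames and keeps range", {
  set.seed(15)
  ema <- feature_track(matrix(rnorm(20 * 14), 20, 14))
  idpath <- warp_path(cbind(1:20, 1:20))
  expect_equal(unclass(transfer_articulation(idpath, ema, 20)),
               unclass(ema), ignore_attr = TRUE)
  # resample to equal length first, as the pipeline does
  B <- matrix(rnorm(15 * 2), 15, 2)
  A <- unclass(resample_to_length(feature_track(B), 20))
  wp <- dtw_align(A, unclass(ema)[, 1:2])
  tr <- transfer_articulation(wp, feature_track(A), 20)
  for (j in 1:2) {
    expect_gte(min(unclass(tr)[, j]), min(A[, j]) - 1e-12)
    expect_lte(max(unclass(tr)[, j]), max(A[, j]) + 1e-12)
  }
  expect_error(transfer_articulation(idpath, ema[1:10, ], 20), "length")
})

test_that("known synthetic warps are recovered and articulation transfers", {
  fx <- small_corpora()
  ref <- fx$ref; pat <- fx$pat
  errs <- numeric(0); cors <- numeric(0); mel_gain <- numeric(0)
  for (i in c(1, 4, 7)) {
    r <- ref$sentences[[i]]; p <- pat$sentences[[i]]
    est <- estimate_patient_ema(
      r$tracks$mel, r$tracks$f0, as.numeric(r$tracks$speech), r$tracks$ema,
      p$tracks$mel, p$tracks$f0, as.numeric(p$tracks$speech))
    n <- n_frames(r$tracks$ema); m <- n_frames(p$tracks$ema)
    truth <- pat$ground_truth$true_warps[[i]]
    # path reference index (resampled scale) -> original reference frames
    est_pos <- vapply(split((est$path[, 1] - 1) * (n - 1) / (m - 1) + 1,
                            est$path[, 2]), mean, numeric(1))
    errs <- c(errs, mean(abs(est_pos - truth)))
    cors <- c(cors, vapply(1:14, function(j)
      stats::cor(unclass(est$ema)[, j], unclass(p$tracks$ema)[, j]),
      numeric(1)))
    # warping the reference mel through the path must beat the identity path
    warped_r <- vapply(1:25, function(j)
      stats::cor(unclass(est$ref_warped_mel)[, j], unclass(p$tracks$mel)[, j]),
      numeric(1))
    ident_r <- vapply(1:25, function(j)
      stats::cor(unclass(resample_to_length(r$tracks$mel, m))[, j],
                 unclass(p$tracks$mel)[, j]), numeric(1))
    mel_gain <- c(mel_gain, mean(warped_r) - mean(ident_r))
  }
  expect_lt(mean(errs), 2)           # mean absolute frame error <= 2 frames
  expect_gt(min(cors), 0.95)         # per-feature transfer correlation
  expect_true(all(mel_gain > 0))
})
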