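make_rec <- function(data, rate = 1000, regions = NULL) {
  montage <- if (!is.null(regions))
    data.frame(channel = paste0("ch", seq_len(nrow(data))), region = regions)
  neural_recording(data, rate, montage)
}

test_that("common median reference removes shared signals", {
  x <- matrix(rep(sin(2 * pi * 50 * (1:2000) / 1000), 4), 4, 2000,
              byrow = TRUE)
  out <- common_median_reference(make_rec(x))
  expect_true(all(out$data == 0))

  expect_error(common_median_reference(make_rec(x[1, , drop = FALSE])),
               ">= 2")

  # after referencing, the across-channel median is zero everywhere, and the
  # operation is idempotent
  set.seed(5)
  y <- matrix(rnorm(5 * 1000), 5, 1000)
  ref1 <- common_median_reference(make_rec(y))
  expect_true(all(abs(apply(ref1$data, 2, stats::median)) < 1e-12))
  ref2 <- common_median_reference(ref1)
  expect_equal(ref1$data, ref2$data)
})

test_that("shared sinusoidal artifact is suppressed by > 20 dB", {
  # three channels built so the across-channel median is exactly zero
  set.seed(6)
  fs <- 1000
  t <- (1:4000) / fs
  x <- rnorm(4000)
  sig <- rbind(x, 0 * x, -x)
  artifact <- 5 * sin(2 * pi * 50 * t)
  contaminated <- sweep(sig, 2, artifact, "+")
  out <- common_median_reference(make_rec(contaminated, fs))
  bp <- function(v) {
    sp <- Mod(stats::fft(v))^2
    f <- (seq_along(v) - 1) * fs / length(v)
    sum(sp[f > 48 & f < 52])
  }
  expect_gt(10 * log10(bp(contaminated[1, ]) / bp(out$data[1, ])), 20)
})

test_that("spectral features: 21 per channel, band structure, frame grid", {
  fs <- 1000
  t <- (1:3000) / fs
  x <- rbind(sin(2 * pi * 55 * t), rnorm(3000))
  feat <- spectral_features(make_rec(x, fs))
  expect_equal(ncol(feat), 2 * 21)
  expect_equal(nrow(feat), 300)
  # 55 Hz sine: per-frame argmax over the 20 bands is the 50-60 Hz band
  bands <- unclass(feat)[, 1:20]
  interior <- 30:270
  expect_true(all(apply(bands[interior, ], 1, which.max) == 6))
  # constant (DC) signal concentrates in the 0-10 Hz band
  dc <- spectral_features(make_rec(rbind(rep(2, 3000), rep(2, 3000)), fs))
  expect_true(all(apply(unclass(dc)[interior, 1:20], 1, which.max) == 1))
  expect_error(spectral_features(make_rec(x[, 1:50], fs)), "shorter")
  expect_error(spectral_features(make_rec(x, 300)), "400")
})

test_that("the 72-electrode montage yields 1,512 features per frame", {
  set.seed(7)
  x <- matrix(rnorm(72 * 600), 72, 600)
  feat <- spectral_features(make_rec(x, 1000))
  expect_equal(ncol(feat), 1512)
})

test_that("band powers are non-negative and approximate signal variance", {
  set.seed(8)
  x <- rbind(rnorm(5000), rnorm(5000))
  feat <- spectral_features(make_rec(x, 1000))
  bands <- unclass(feat)[, 1:20]
  expect_true(all(bands >= 0))
  # Parseval: total band power (x bandwidth) approximates the variance of
  # the white signal below 200 Hz (i.e. 40% of total variance) within 5%
  interior <- 50:450
  est <- mean(rowSums(bands[interior, ]) * 10)    # 10 Hz per band
  expect_lt(abs(est / 0.4 - 1), 0.05)
})

test_that("region selection splits the montage cleanly", {
  set.seed(9)
  x <- matrix(rnorm(6 * 1000), 6, 1000)
  regions <- c("frontal", "frontal", "temporal", "temporal", "temporal",
               "frontal")
  feat <- spectral_features(make_rec(x, 1000, regions))
  expect_identical(select_region(feat, "all"), feat)
  fr <- select_region(feat, "frontal")
  te <- select_region(feat, "temporal")
  expect_equal(ncol(fr), 3 * 21)
  expect_equal(ncol(te), 3 * 21)
  expect_setequal(c(colnames(fr), colnames(te)), colnames(feat))
  expect_error(select_region(feat, "parietal"))
  # the real montage's frontal count: 28 electrodes -> 588 features
  expect_equal(28 * 21, 588)
})

test_that("context windowing concatenates the right frames", {
  m <- feature_track(cbind(1:50, 101:150))
  expect_equal(unclass(window_features(m, windowing_config(0, 0))),
               unclass(m), ignore_attr = TRUE)

  w <- window_features(m, windowing_config(210, 0))
  expect_equal(ncol(w), 2 * 21)
  # interior frame t concatenates x(t-10)..x(t+10)
  expect_equal(as.numeric(unclass(w)[20, seq(1, 41, 2)]), 10:30)

  # context 210 ms with delay -100 ms: the window spans [t-200 ms, t]
  wd <- window_features(m, windowing_config(210, -100))
  expect_equal(as.numeric(unclass(wd)[30, seq(1, 41, 2)]), 10:30)

  expect_error(window_features(m, windowing_config(210 * 10, 0)), "larger")
})

test_that("windowing commutes with concatenation away from boundaries", {
  set.seed(10)
  a <- feature_track(matrix(rnorm(40 * 3), 40, 3))
  b <- feature_track(matrix(rnorm(30 * 3), 30, 3))
  cfg <- windowing_config(110, 0)
  joint <- window_features(feature_track(rbind(unclass(a), unclass(b))), cfg)
  separate <- rbind(unclass(window_features(a, cfg)),
                    unclass(window_features(b, cfg)))
  interior <- c(6:34, 46:64)
  expect_equal(unclass(joint)[interior, ], separate[interior, ],
               ignore_attr = TRUE)
})
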