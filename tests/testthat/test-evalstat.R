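test_that("the overt-sentence protocol arithmetic gives 641 sentences", {
  p <- default_protocol()
  expect_equal(sum(p$read), 391)
  expect_equal(sum(p$repeated), 250)
  expect_equal(count_overt_sentences(), 641)
})

test_that("per-sentence Pearson handles perfect, inverted and flat signals", {
  set.seed(30)
  y <- matrix(rnorm(100 * 3), 100, 3)
  expect_equal(as.numeric(pearson_per_sentence(y, y)), rep(1, 3))
  expect_equal(as.numeric(pearson_per_sentence(-y, y)), rep(-1, 3))
  flat <- y; flat[, 2] <- 0
  r <- pearson_per_sentence(flat, y)
  expect_equal(as.numeric(r[2]), 0)
  expect_true(attr(r, "degenerate")[2])
  expect_error(pearson_per_sentence(y[1:50, ], y), "mismatch")
})

test_that("Wilcoxon signed-rank matches exact enumeration and corrects p", {
  set.seed(31)
  for (case in 1:8) {
    n <- sample(5:10, 1)
    real <- rnorm(n); chance <- rnorm(n)
    # avoid ties in |differences| so the exact path applies
    res <- wilcoxon_bonferroni(real, chance)
    expect_equal(res$p_raw, wilcoxon_enum_p(real - chance),
                 tolerance = 1e-12)
  }
  same <- rnorm(10)
  res0 <- wilcoxon_bonferroni(same, same)
  expect_equal(res0$p_corrected, 1)
  expect_true(res0$all_zero)

  r <- wilcoxon_bonferroni(rnorm(12) + 2, rnorm(12), m = 5)
  expect_equal(r$p_corrected, min(1, 5 * r$p_raw))

  # large-sample path agrees with the base-R normal approximation
  set.seed(32)
  a <- rnorm(60, 0.3); b <- rnorm(60)
  mine <- wilcoxon_bonferroni(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-8)
})

test_that("Quade omnibus agrees with stats::quade.test and the permutation
           oracle", {
  set.seed(33)
  y <- matrix(rnorm(8 * 3), 8, 3) + matrix(rep(c(0, 0.8, 1.6), each = 8),
                                           8, 3)
  mine <- quade_conover(y)
  ref <- stats::quade.test(y)
  expect_equal(as.numeric(mine$statistic), as.numeric(ref$statistic),
               tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_equal(mine$df, as.numeric(unlist(ref$parameter)),
               ignore_attr = TRUE)

  # permutation oracle on a crafted 8 x 3 design
  perm_p <- quade_perm_p(y, nperm = 20000)
  se <- sqrt(perm_p * (1 - perm_p) / 20000)
  expect_lt(abs(mine$p - perm_p), max(4 * se, 5e-3))

  ties <- matrix(rep(1:8, 3), 8, 3)
  deg <- quade_conover(ties)
  expect_equal(deg$p, 1)
  expect_true(deg$degenerate)
  expect_error(quade_conover(y[, 1, drop = FALSE]), ">= 2")
})

test_that("Conover pairwise comparisons separate shifted treatments", {
  set.seed(34)
  y <- cbind(rnorm(12), rnorm(12), rnorm(12) + 3)
  res <- quade_conover(y)
  expect_lt(res$p, 0.01)
  expect_lt(res$pairwise_p[1, 3], 0.01)
  expect_lt(res$pairwise_p[2, 3], 0.01)
  expect_gt(res$pairwise_p[1, 2], 0.05)
  expect_true(all(res$pairwise_p >= 0 & res$pairwise_p <= 1))
})

test_that("fold assignment covers every sentence once with balanced sizes", {
  cond <- rep(c("read", "repeat"), times = c(13, 10))
  folds <- ecogspeech:::make_folds(cond, 5, seed = 3)
  expect_equal(length(folds), 23)
  sizes <- table(folds)
  expect_lte(max(sizes) - min(sizes), 1)
  folds2 <- ecogspeech:::make_folds(cond, 5, seed = 3)
  expect_identical(folds, folds2)
})

test_that("cross-validated direct decoding is leak-free and near-perfect on
           a noise-free corpus", {
  fx <- small_corpora()
  dd <- build_decoding_data(fx$pat)
  cfg <- experiment_config("direct", decoder = "ridge_cv",
                           windowing = windowing_config(110, 0),
                           n_pca = 60, n_folds = 4, seed = 5)
  tab <- crossval_run(dd, cfg)
  expect_s3_class(tab, "eval_table")
  # every sentence tested exactly once
  pearson <- tab[tab$metric == "pearson", ]
  expect_equal(sort(unique(pearson$sentence_id)),
               sort(vapply(dd$sentences, `[[`, "", "id")))
  expect_equal(nrow(pearson), 12 * 26)
  expect_gt(stats::median(pearson$value[grepl("^c", pearson$feature)]), 0.95)

  # train-only fitting: altering a test sentence's neural data does not
  # change a decoder fitted on the training sentences
  neural <- lapply(dd$sentences, `[[`, "neural")
  mel <- lapply(dd$sentences, `[[`, "mel")
  m1 <- train_decoder(neural[1:8], mel[1:8], "ols",
                      windowing_config(0, 0), n_pca = 20)
  neural[[12]] <- feature_track(unclass(neural[[12]]) * 5)
  m2 <- train_decoder(neural[1:8], mel[1:8], "ols",
                      windowing_config(0, 0), n_pca = 20)
  expect_identical(m1$preproc$zx, m2$preproc$zx)
  expect_identical(m1$weights, m2$weights)
})

test_that("chance shuffling destroys decoding and is reproducible", {
  fx <- small_corpora()
  dd <- build_decoding_data(fx$pat)
  cfg <- experiment_config("direct", decoder = "ols",
                           windowing = windowing_config(0, 0),
                           n_pca = 30, n_folds = 4, seed = 5)
  ch1 <- chance_levels(dd, cfg, seed = 77)
  ch2 <- chance_levels(dd, cfg, seed = 77)
  expect_identical(ch1, ch2)
  r_ch <- ch1$value[ch1$metric == "pearson"]
  expect_lt(abs(stats::median(r_ch)), 0.05)
  expect_true(all(ch1$condition == "chance"))

  real <- crossval_run(dd, cfg)
  r_re <- real$value[real$metric == "pearson" & grepl("^c", real$feature)]
  r_ch_mel <- r_ch[grepl("^c", ch1$feature[ch1$metric == "pearson"])]
  wt <- wilcoxon_bonferroni(r_re, r_ch_mel)
  expect_lt(wt$p_corrected, 0.001)
})

test_that("evaluation summaries aggregate by feature group", {
  tab <- data.frame(sentence_id = "s", fold = 1,
                    feature = c("c0", "c1", "f0", "ema3"),
                    metric = "pearson", value = c(0.5, 0.7, 0.9, 0.2),
                    condition = "real")
  s <- summarize_eval(tab)
  expect_equal(as.numeric(s["mel"]), 0.6)
  expect_equal(as.numeric(s["f0"]), 0.9)
  expect_equal(as.numeric(s["ema"]), 0.2)
})

test_that("the sweep harness runs the comparison grids end to end", {
  fx <- small_corpora()
  dd <- build_decoding_data(fx$pat)
  base <- experiment_config("direct", decoder = "ols",
                            windowing = windowing_config(50, 0),
                            n_pca = 20, n_folds = 3, seed = 4)
  sw <- run_sweep(dd, base, pca_sizes = 20, contexts_ms = c(0, 50),
                  delays_ms = 0, pls_components = 6)
  expect_equal(nrow(sw), 5)
  expect_true(all(is.finite(sw$median_mel_r)))
  expect_setequal(unique(sw$sweep),
                  c("pca_size", "context_ms", "delay_ms", "pls_components"))
})
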