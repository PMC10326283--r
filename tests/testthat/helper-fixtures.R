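# Shared fixtures, built once per test run.

clamp_idx_test <- function(i, n) pmin(pmax(i, 1L), n)

# evaluate code under a fixed seed, restoring the RNG afterwards
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# a fully voiced time-varying vowel with a natural spectral tilt, plus its
# vocoder parameters
make_test_vowel <- function(n = 240, f0_hz = 140) {
  tt <- (seq_len(n) - 1) / 100
  mel <- matrix(0, n, 25)
  mel[, 1] <- -2 + 0.7 * sin(2 * pi * 0.7 * tt)
  mel[, 2] <- 1.0 + 0.3 * sin(2 * pi * 0.5 * tt)
  for (j in 3:25)
    mel[, j] <- (0.5 / (j - 1)^0.5) * sin(2 * pi * (0.3 + 0.11 * j) * tt +
                                            1.7 * j)
  list(mel = feature_track(mel, labels = paste0("c", 0:24)),
       f0 = feature_track(rep(f0_hz, n), labels = "f0"))
}

# small paired corpora cache (expensive; reused across test files)
.fixture_env <- new.env(parent = emptyenv())

small_corpora <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- synth_config(n_sentences = 12, n_electrodes = 8,
                        duration_range = c(2, 3), noise_sd = 0,
                        warp_strength = 0.3, seed = 421)
    ref <- make_reference_corpus(cfg, synthesize_audio = FALSE)
    pat <- make_patient_corpus(ref, cfg, synthesize_audio = FALSE)
    .fixture_env$small <- list(cfg = cfg, ref = ref, pat = pat)
  }
  .fixture_env$small
}

# brute-force DTW oracle: memoized recursion over all monotone paths
dtw_oracle_cost <- function(D) {
  n <- nrow(D); m <- ncol(D)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (i < 1 || j < 1) return(Inf)
    if (i == 1 && j == 1) return(D[1, 1])
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- D[i, j] + min(rec(i - 1, j - 1), rec(i - 1, j), rec(i, j - 1))
    memo[i, j] <<- v
    v
  }
  rec(n, m)
}

# exact Wilcoxon signed-rank two-sided p by full 2^n sign enumeration
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% rk
  mu <- n * (n + 1) / 4
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
}

# Quade permutation oracle: null distribution by permuting treatment labels
# within blocks (the block weights are permutation-invariant)
quade_perm_p <- function(values, nperm = 20000, seed = 99) {
  obs <- quade_conover(values)$statistic
  n <- nrow(values); k <- ncol(values)
  r <- t(apply(values, 1, rank))
  Q <- rank(apply(values, 1, function(x) diff(range(x))))
  stat_from_ranks <- function(rm) {
    S <- Q * (rm - (k + 1) / 2)
    A <- sum(S^2); B <- sum(colSums(S)^2) / n
    if (A - B <= 0) return(Inf)
    (n - 1) * B / (A - B)
  }
  set.seed(seed)
  cnt <- 0L
  for (p in seq_len(nperm)) {
    rm <- t(apply(r, 1, sample))
    if (stat_from_ranks(rm) >= obs - 1e-12) cnt <- cnt + 1L
  }
  (cnt + 1) / (nperm + 1)
}
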