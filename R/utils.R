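# Shared numerical helpers.

# Shape-preserving piecewise-cubic interpolation (pchip). Clamps query points
# to the data range so downstream rounding at the end of a grid cannot step
# outside the support.
pchip_interp <- function(x, y, xq) {
  xq <- pmin(pmax(xq, x[1]), x[length(x)])
  if (length(x) < 3) {
    stats::approx(x, y, xout = xq, rule = 2)$y
  } else {
    pracma::pchip(x, y, xq)
  }
}

# Symmetric (mirror) padding of a vector by n samples on each side.
sym_pad <- function(x, n) {
  len <- length(x)
  n <- min(n, len - 1L)
  c(x[(n + 1L):2L], x, x[(len - 1L):(len - n)])
}

# Mirror-clamped index helper: reflects indices into [1, n] by edge replication.
clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

# RMS in dBFS (full scale = 1).
rms_db <- function(x) 20 * log10(sqrt(mean(x^2)))

# Root-raised utility: scale signal to a target RMS level in dBFS.
set_loudness <- function(x, target_db = -20) {
  r <- sqrt(mean(x^2))
  if (r == 0) stop("cannot set loudness of an all-zero signal")
  x * 10^(target_db / 20) / r
}

# Soft limiter: tanh shaping above a threshold to avoid clipping, transparent
# below it.
soft_limit <- function(x, threshold = 0.98) {
  over <- abs(x) > threshold
  x[over] <- sign(x[over]) * (threshold + (1 - threshold) *
                                tanh((abs(x[over]) - threshold) / (1 - threshold)))
  x
}

# Zero-based run-length encoding of a logical vector -> (start, end) frame
# indices (1-based, inclusive) of TRUE runs.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Remove TRUE runs shorter than min_len frames.
drop_short_runs <- function(flag, min_len) {
  runs <- true_runs(flag)
  if (nrow(runs) == 0) return(flag)
  for (k in seq_len(nrow(runs))) {
    if (runs[k, "end"] - runs[k, "start"] + 1L < min_len)
      flag[runs[k, "start"]:runs[k, "end"]] <- FALSE
  }
  flag
}

# Deterministic child seed derived from a base seed and a stream label.
# Kept below 2^31 - 1.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(seed) * 7919 + h * 104729) %% 2147483587 + 1
}

# Evaluate an expression under a local RNG state (restores the caller's RNG).
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  code
}

# 1/f ("pink") shaped Gaussian noise of length n, unit variance.
pink_noise <- function(n) {
  nfft <- stats::nextn(n, 2)
  spec <- stats::fft(stats::rnorm(nfft))
  f <- c(1, seq_len(nfft - 1))
  f <- pmin(f, nfft - f + 1)           # symmetric frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  as.numeric(scale(x))
}
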