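# Acoustic processing: audio preprocessing, speech detection, mel-cepstral
# and F0 analysis, pitch reconstruction, and vocoder resynthesis.
#
# The spectral-envelope representation is an order-24 mel cepstrum: the log
# amplitude spectrum is evaluated on an all-pass warped frequency axis
# (warping constant alpha = 0.455 approximates the mel scale at 22,050 Hz)
# and truncated to its first 25 cosine coefficients c_0..c_24. Synthesis
# drives the per-frame warped envelope with an impulse-train (voiced) or
# white-noise (unvoiced) excitation and overlap-adds the filtered frames.

MEL_ORDER <- 24L
MEL_ALPHA <- 0.455
MEL_WINDOW <- 400L     # Blackman analysis window, samples at 22,050 Hz
MEL_SHIFT <- 220L      # frame shift, samples -> native rate ~100.23 Hz
MEL_NFFT <- 1024L
MEL_EPS <- 1e-4        # periodogram floor
AUDIO_RATE <- 22050
FRAME_RATE <- 100      # common feature frame rate, Hz
F0_MIN <- 80
F0_MAX <- 300

# all-pass frequency warp: omega (rad) -> warped omega, parameter a in (-1,1)
warp_freq <- function(omega, a) {
  omega + 2 * atan(a * sin(omega) / (1 - a * cos(omega)))
}

#' Preprocess an audio waveform
#'
#' Removes DC offset, peak-normalizes, sets the average level to -20 dBFS by
#' automatic gain control, and resamples to 22,050 Hz with an anti-aliasing
#' low-pass filter.
#'
#' @param w a `waveform`.
#' @param target_rate output sampling rate (default 22,050 Hz).
#' @return a preprocessed `waveform`.
#' @export
preprocess_audio <- function(w, target_rate = AUDIO_RATE) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  if (length(x) == 0 || all(x == 0)) stop("cannot normalize all-zero audio")
  x <- x - mean(x)
  if (all(x == 0)) stop("cannot normalize constant audio")
  x <- x / max(abs(x))                     # peak-normalize
  x <- set_loudness(x, -20)                # AGC to -20 dBFS
  if (w$rate != target_rate) {
    # rational resampling with anti-aliasing FIR
    g <- gcd_int(round(target_rate), round(w$rate))
    x <- as.numeric(signal::resample(x, round(target_rate) / g,
                                     round(w$rate) / g))
  }
  waveform(x, target_rate)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Detect speech segments from the audio envelope
#'
#' Hilbert-magnitude envelope, smoothed by a 100 ms moving average; frames
#' above 10% of the per-sentence envelope maximum for at least 50 ms count as
#' speech; segments closer than 100 ms are merged.
#'
#' @param w a preprocessed `waveform`.
#' @param threshold_frac envelope threshold as a fraction of the smoothed
#'   envelope maximum (default 0.10).
#' @return a `speech_segments` data frame with columns `onset`, `offset`
#'   (seconds).
#' @export
detect_speech <- function(w, threshold_frac = 0.10) {
  stopifnot(inherits(w, "waveform"))
  env <- hilbert_envelope(w$samples)
  win <- max(1L, round(0.100 * w$rate))
  smooth <- as.numeric(stats::filter(sym_pad(env, win), rep(1 / win, win),
                                     sides = 2))
  smooth <- smooth[(win + 1):(win + length(env))]
  thr <- threshold_frac * max(smooth)
  flag <- smooth > thr & thr > 0
  flag[is.na(flag)] <- FALSE
  flag <- drop_short_runs(flag, max(1L, round(0.050 * w$rate)))
  runs <- true_runs(flag)
  segs <- if (nrow(runs) == 0) {
    data.frame(onset = numeric(), offset = numeric())
  } else {
    on <- (runs[, "start"] - 1L) / w$rate
    off <- runs[, "end"] / w$rate
    # merge segments separated by less than 100 ms
    keep_on <- on[1]; out_on <- c(); out_off <- c()
    cur_off <- off[1]
    if (length(on) > 1) {
      for (k in 2:length(on)) {
        if (on[k] - cur_off < 0.100) {
          cur_off <- off[k]
        } else {
          out_on <- c(out_on, keep_on); out_off <- c(out_off, cur_off)
          keep_on <- on[k]; cur_off <- off[k]
        }
      }
    }
    data.frame(onset = c(out_on, keep_on), offset = c(out_off, cur_off))
  }
  class(segs) <- c("speech_segments", "data.frame")
  segs
}

hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Sample speech segments on the 100 Hz frame grid
#'
#' @param segs a `speech_segments` object.
#' @param n number of output frames.
#' @param rate frame rate in Hz (default 100).
#' @return numeric 0/1 vector of length `n` (frame k covers centre t = k/rate).
#' @export
speech_flag <- function(segs, n, rate = FRAME_RATE) {
  t <- (seq_len(n) - 1) / rate
  flag <- numeric(n)
  for (k in seq_len(nrow(segs)))
    flag[t >= segs$onset[k] & t < segs$offset[k]] <- 1
  flag
}

# Frame a signal into columns: centers (sample indices, 1-based), window
# length L; symmetric padding at edges.
frame_signal <- function(x, centers, L) {
  half <- L %/% 2
  xp <- sym_pad(x, half + 1L)
  idx <- outer(seq_len(L) - half - 1L, centers + half + 1L, `+`)
  matrix(xp[idx], nrow = L)
}

#' Mel-cepstral analysis of a waveform
#'
#' Order-24 mel cepstrum (25 coefficients per frame): Blackman windows of 400
#' samples, 220-sample frame shift, 1,024-point FFT with a 1e-4 periodogram
#' floor, all-pass warping constant 0.455. The native ~100.23 Hz frame rate
#' is resampled to exactly 100 Hz by shape-preserving piecewise-cubic
#' interpolation; the output has `round(duration * 100)` frames.
#'
#' @param w a `waveform` at 22,050 Hz.
#' @return a `feature_track` (frames x 25, labels `c0`..`c24`) at 100 Hz.
#' @export
mel_analysis <- function(w) {
  stopifnot(inherits(w, "waveform"))
  if (w$rate != AUDIO_RATE) stop("mel_analysis expects 22,050 Hz audio")
  n <- length(w$samples)
  if (n < MEL_WINDOW) stop("audio shorter than one analysis window")
  centers <- seq(1L, n, by = MEL_SHIFT)
  frames <- frame_signal(w$samples, centers, MEL_WINDOW)
  win <- signal::blackman(MEL_WINDOW)
  frames <- frames * win
  spec <- stats::mvfft(rbind(frames,
                             matrix(0, MEL_NFFT - MEL_WINDOW, ncol(frames))))
  half <- MEL_NFFT / 2
  pw <- Mod(spec[1:(half + 1), , drop = FALSE])^2 / sum(win^2)
  pw <- pmax(pw, MEL_EPS)
  logamp <- 0.5 * log(pw)
  # resample log spectrum onto a uniform warped-frequency grid
  wt <- pi * (0:half) / half                        # uniform warped grid
  om <- warp_freq(wt, -MEL_ALPHA)                   # corresponding linear freq
  pos <- om / pi * half + 1                         # fractional bin index
  i0 <- pmin(floor(pos), half)                      # linear interpolation
  frac <- pos - i0
  la_w <- logamp[i0, , drop = FALSE] * (1 - frac) +
    logamp[pmin(i0 + 1, half + 1), , drop = FALSE] * frac
  # even symmetric extension -> real cepstrum on the warped axis
  full <- rbind(la_w, la_w[half:2, , drop = FALSE])
  cep <- Re(stats::mvfft(full)) / MEL_NFFT
  mel_native <- t(cep[1:(MEL_ORDER + 1), , drop = FALSE])
  # native frame times -> 100 Hz grid
  t_native <- (centers - 1) / AUDIO_RATE
  dur <- n / AUDIO_RATE
  n_out <- round(dur * FRAME_RATE)
  t_out <- (seq_len(n_out) - 1) / FRAME_RATE
  out <- vapply(seq_len(MEL_ORDER + 1), function(j)
    pchip_interp(t_native, mel_native[, j], t_out), numeric(n_out))
  feature_track(out, rate = FRAME_RATE, labels = paste0("c", 0:MEL_ORDER))
}

#' Extract F0 (fundamental frequency) from a waveform
#'
#' Normalized-autocorrelation pitch estimator constrained to 80-300 Hz, with
#' the same 220-sample frame shift as the mel analysis. 0 denotes unvoiced.
#' The native track is resampled to 100 Hz by nearest-neighbor interpolation
#' (preserving voicing discontinuities) and voiced runs shorter than 50 ms
#' are zeroed.
#'
#' @param w a `waveform` at 22,050 Hz.
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced (default 0.5).
#' @return a one-column `feature_track` (`f0`, Hz) at 100 Hz.
#' @export
extract_f0 <- function(w, voicing_threshold = 0.5) {
  stopifnot(inherits(w, "waveform"))
  if (w$rate != AUDIO_RATE) stop("extract_f0 expects 22,050 Hz audio")
  fs <- w$rate
  n <- length(w$samples)
  L <- 2L * (round(fs / F0_MIN) + 8L)       # window long enough for 2 periods
  if (n < L) stop("audio shorter than one pitch analysis window")
  lag_min <- floor(fs / F0_MAX)
  lag_max <- ceiling(fs / F0_MIN)
  centers <- seq(1L, n, by = MEL_SHIFT)
  # restrict to the low spectrum: pitch periodicity lives below ~2.5 kHz and
  # broadband energy above it only destabilizes the autocorrelation
  lp <- signal::butter(4, 2500 / (fs / 2), type = "low")
  xs <- as.numeric(signal::filtfilt(lp, w$samples))
  frames <- frame_signal(xs, centers, L)
  frames <- sweep(frames, 2, colMeans(frames))
  f0_native <- vapply(seq_len(ncol(frames)), function(k) {
    x <- frames[, k]
    e0 <- sum(x^2)
    if (e0 <= 0) return(0)
    # normalized autocorrelation over candidate lags via FFT
    nf <- stats::nextn(2L * L, 2)
    X <- stats::fft(c(x, numeric(nf - L)))
    ac <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[1:(lag_max + 1)] / nf
    # unbiased normalization: the raw estimator sums L - lag products
    r <- (ac[(lag_min:lag_max) + 1L] / ac[1]) * (L / (L - lag_min:lag_max))
    pk <- max(r)
    if (pk < voicing_threshold) return(0)
    # among local maxima, take the shortest lag within 90% of the best peak
    # (octave-error guard)
    nl <- length(r)
    is_peak <- c(FALSE, r[2:(nl - 1)] > r[1:(nl - 2)] &
                   r[2:(nl - 1)] >= r[3:nl], FALSE)
    is_peak[which.max(r)] <- TRUE
    cand <- which(is_peak & r >= 0.9 * pk)
    lag <- lag_min + cand[1] - 1L
    # parabolic refinement
    if (lag > lag_min && lag < lag_max) {
      i <- lag - lag_min + 1L
      d <- (r[i - 1] - r[i + 1]) / (2 * (r[i - 1] - 2 * r[i] + r[i + 1]))
      if (is.finite(d) && abs(d) < 1) lag <- lag + d
    }
    f <- fs / lag
    if (f < F0_MIN || f > F0_MAX) 0 else f
  }, numeric(1))
  # nearest-neighbor resample to 100 Hz
  t_native <- (centers - 1) / fs
  n_out <- round(n / fs * FRAME_RATE)
  t_out <- (seq_len(n_out) - 1) / FRAME_RATE
  idx <- vapply(t_out, function(t) which.min(abs(t_native - t)), integer(1))
  f0 <- f0_native[idx]
  voiced <- drop_short_runs(f0 > 0, round(0.050 * FRAME_RATE))
  f0[!voiced] <- 0
  feature_track(f0, rate = FRAME_RATE, labels = "f0")
}

#' Reconstruct the excitation pitch period from F0
#'
#' pitch = fs / f0 samples per period for voiced frames, 0 for unvoiced.
#'
#' @param f0 F0 values in Hz (0 = unvoiced); vector or one-column track.
#' @param fs sampling rate in Hz.
#' @return pitch period in samples per frame (0 where unvoiced).
#' @export
f0_to_pitch <- function(f0, fs) {
  f0 <- as.numeric(f0)
  if (fs <= 0) stop("fs must be > 0")
  if (any(f0 < 0)) stop("negative F0")
  ifelse(f0 == 0, 0, fs / f0)
}

#' Synthesize audio from mel cepstrum and F0
#'
#' The per-frame warped spectral envelope (from c_0..c_24, alpha = 0.455) is
#' excited by an impulse train at the reconstructed pitch period when voiced
#' and white noise when unvoiced; frames are filtered in the frequency domain
#' and overlap-added. Output is peak-normalized, soft-limited and set to
#' -20 dBFS.
#'
#' @param mel a 25-column mel `feature_track` at 100 Hz.
#' @param f0 an aligned one-column F0 `feature_track` (or numeric vector), Hz.
#' @param fs output sampling rate (default 22,050 Hz).
#' @return a `waveform`.
#' @export
mlsa_synthesize <- function(mel, f0, fs = AUDIO_RATE) {
  f0 <- as.numeric(f0)
  if (nrow(mel) == 0 || length(f0) == 0) stop("empty tracks")
  if (ncol(mel) != MEL_ORDER + 1) stop("mel track must have 25 coefficients")
  if (nrow(mel) != length(f0)) stop("mel / F0 frame-count mismatch")
  nfr <- nrow(mel)
  hop <- fs / FRAME_RATE                      # 220.5 samples at 22,050 Hz
  n <- round(nfr * hop)
  # per-sample f0 (piecewise constant over frames)
  fr_of_sample <- clamp_idx(floor((seq_len(n) - 1) / hop) + 1L, nfr)
  f0_s <- f0[fr_of_sample]
  exc <- numeric(n)
  unv <- f0_s == 0
  exc[unv] <- stats::rnorm(sum(unv))
  # impulse train through voiced runs, period fs/f0 at the current sample
  runs <- true_runs(!unv)
  if (nrow(runs) > 0) {
    for (k in seq_len(nrow(runs))) {
      t <- as.numeric(runs[k, "start"])
      while (t <= runs[k, "end"]) {
        per <- fs / f0_s[floor(t)]
        exc[round(t)] <- sqrt(per)
        t <- t + per
      }
    }
  }
  # frequency-domain envelope per frame; frames are zero-padded to twice the
  # window length before filtering so the zero-phase envelope response
  # overlap-adds as a linear (not circular) convolution
  L <- 512L
  half <- L / 2
  nfft <- 2L * L
  wt <- warp_freq(pi * (0:L) / L, MEL_ALPHA)         # warped freq of each bin
  Cmat <- cbind(1, 2 * cos(outer(wt, 1:MEL_ORDER)))  # (L+1) x 25
  Henv <- exp(Cmat %*% t(unclass(mel)))              # (L+1) x nfr amplitude
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)   # hann
  margin <- nfft
  out <- numeric(n + 2L * margin)
  wsum <- numeric(n + 2L * margin)
  for (k in seq_len(nfr)) {
    c0 <- round((k - 1) * hop) + 1L
    seg_idx <- (c0 - half):(c0 + half - 1L)
    seg <- numeric(L)
    valid <- seg_idx >= 1 & seg_idx <= n
    seg[valid] <- exc[seg_idx[valid]]
    S <- stats::fft(c(seg * win, numeric(nfft - L)))
    Hfull <- c(Henv[, k], Henv[L:2, k])
    y <- Re(stats::fft(S * Hfull, inverse = TRUE)) / nfft
    # zero-phase response: buffer indices 1..3L/2 are times 0..3L/2-1 from
    # the segment start, the wrapped tail holds times -L/2..-1
    s0 <- c0 - half + margin                  # segment start in out[]
    fwd <- 3L * half                          # 3L/2 forward samples
    out[s0:(s0 + fwd - 1L)] <- out[s0:(s0 + fwd - 1L)] + y[1:fwd]
    out[(s0 - half):(s0 - 1L)] <- out[(s0 - half):(s0 - 1L)] +
      y[(fwd + 1L):nfft]
    wsum[s0:(s0 + L - 1L)] <- wsum[s0:(s0 + L - 1L)] + win
  }
  y <- out[(margin + 1):(margin + n)] / pmax(wsum[(margin + 1):(margin + n)],
                                             1e-6)
  if (all(y == 0)) y[1] <- 1e-12
  y <- y / max(abs(y))
  y <- soft_limit(y)
  y <- set_loudness(y, -20)
  waveform(y, fs)
}
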