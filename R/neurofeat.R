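# Neural signal processing: common median referencing, spectral feature
# extraction (20 x 10 Hz band powers up to 200 Hz plus a 0.5-5 Hz component
# per electrode), electrode-region selection, and context/delay windowing.

N_BANDS <- 20L
FEATS_PER_CHANNEL <- N_BANDS + 1L   # 21: 20 band powers + lowfreq 0.5-5 Hz

#' Multichannel neural recording
#'
#' @param data channels x samples numeric matrix.
#' @param rate sampling rate in Hz.
#' @param montage data frame with columns `channel` (label) and `region`
#'   ("frontal" or "temporal"); defaults to all-"frontal" labels.
#' @return an object of class `neural_recording`.
#' @export
neural_recording <- function(data, rate, montage = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 1) stop("need at least one channel")
  if (rate <= 0) stop("rate must be > 0")
  if (is.null(montage)) {
    montage <- data.frame(channel = paste0("ch", seq_len(nrow(data))),
                          region = "frontal")
  }
  if (nrow(montage) != nrow(data))
    stop("montage rows must match channel count")
  structure(list(data = data, rate = rate, montage = montage),
            class = "neural_recording")
}

#' @export
print.neural_recording <- function(x, ...) {
  cat(sprintf("<neural_recording> %d channels x %d samples @ %g Hz (%s)\n",
              nrow(x$data), ncol(x$data), x$rate,
              paste(sprintf("%s:%d", names(table(x$montage$region)),
                            table(x$montage$region)), collapse = ", ")))
  invisible(x)
}

#' Common median reference
#'
#' Subtracts the across-channel median from every channel at each sample,
#' removing signals shared by all electrodes (line noise, electromagnetic
#' interference). More robust to outlier channels than a common average.
#'
#' @param rec a `neural_recording` with at least 2 channels.
#' @return a re-referenced `neural_recording`.
#' @export
common_median_reference <- function(rec) {
  stopifnot(inherits(rec, "neural_recording"))
  if (nrow(rec$data) < 2) stop("common median reference needs >= 2 channels")
  med <- apply(rec$data, 2, stats::median)
  rec$data <- sweep(rec$data, 2, med)
  rec
}

#' Neural spectral features
#'
#' Per channel: short-time power spectral density over 200 ms Hamming windows
#' shifted by 10 ms (periodogram, symmetric edge padding), averaged within
#' each 10 Hz band from 0 to 200 Hz (20 bands), plus the 0.5-5 Hz band-passed
#' raw signal sampled on the same 100 Hz grid -- 21 features per channel.
#'
#' @param rec a `neural_recording` with rate >= 400 Hz.
#' @return a `feature_track` (frames x channels*21) at 100 Hz, with labels
#'   `<channel>.b<lo>_<hi>` and `<channel>.lowfreq`; channel regions are kept
#'   in the `montage` attribute.
#' @export
spectral_features <- function(rec) {
  stopifnot(inherits(rec, "neural_recording"))
  fs <- rec$rate
  if (fs < 400) stop("sampling rate must be >= 400 Hz for 0-200 Hz bands")
  nsamp <- ncol(rec$data)
  L <- round(0.200 * fs)
  if (nsamp < L) stop("recording shorter than one analysis window")
  hop <- fs / 100
  n_out <- round(nsamp / fs * 100)
  centers <- round((seq_len(n_out) - 1) * hop) + 1L
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))   # Hamming
  nfft <- stats::nextn(L, 2)
  freqs <- (0:(nfft / 2)) * fs / nfft
  band_of <- findInterval(freqs, seq(0, 200, by = 10),
                          rightmost.closed = FALSE)
  keep <- band_of >= 1 & band_of <= N_BANDS & freqs < 200
  # 0.5-5 Hz band-pass as a high-pass/low-pass cascade: a single high-order
  # narrow band-pass at this rate is numerically unstable
  hp_filt <- signal::butter(2, 0.5 / (fs / 2), type = "high")
  lp_filt <- signal::butter(4, 5 / (fs / 2), type = "low")
  nch <- nrow(rec$data)
  out <- matrix(0, n_out, nch * FEATS_PER_CHANNEL)
  labels <- character(nch * FEATS_PER_CHANNEL)
  for (ch in seq_len(nch)) {
    x <- rec$data[ch, ]
    frames <- frame_signal(x, centers, L) * win
    spec <- stats::mvfft(rbind(frames, matrix(0, nfft - L, ncol(frames))))
    psd <- Mod(spec[1:(nfft / 2 + 1), , drop = FALSE])^2 / (fs * sum(win^2))
    psd[2:(nfft / 2), ] <- 2 * psd[2:(nfft / 2), ]      # one-sided density
    bands <- rowsum(psd[keep, , drop = FALSE], band_of[keep])
    bands <- bands / as.numeric(table(band_of[keep]))
    low <- as.numeric(signal::filtfilt(lp_filt,
                                       signal::filtfilt(hp_filt, x)))
    low <- low[clamp_idx(centers, nsamp)]
    cols <- (ch - 1) * FEATS_PER_CHANNEL + seq_len(FEATS_PER_CHANNEL)
    out[, cols] <- cbind(t(bands), low)
    lab <- rec$montage$channel[ch]
    labels[cols] <- c(sprintf("%s.b%d_%d", lab, seq(0, 190, 10),
                              seq(10, 200, 10)),
                      sprintf("%s.lowfreq", lab))
  }
  ft <- feature_track(out, rate = 100, labels = labels)
  attr(ft, "montage") <- rec$montage
  attr(ft, "channels") <- rec$montage$channel
  ft
}

#' Select neural features by electrode region
#'
#' @param feat a `feature_track` produced by [spectral_features()] (carries a
#'   montage attribute).
#' @param region "frontal", "temporal" or "all".
#' @return the restricted `feature_track`.
#' @export
select_region <- function(feat, region = c("all", "frontal", "temporal")) {
  region <- match.arg(region)
  if (region == "all") return(feat)
  montage <- attr(feat, "montage")
  if (is.null(montage)) stop("feature track carries no montage")
  keep_ch <- montage$channel[montage$region == region]
  if (length(keep_ch) == 0) stop("no channels tagged '", region, "'")
  ch_of_col <- rep(montage$channel, each = FEATS_PER_CHANNEL)
  sel <- ch_of_col %in% keep_ch
  out <- feature_track(unclass(feat)[, sel, drop = FALSE],
                       rate = frame_rate(feat),
                       labels = colnames(feat)[sel])
  attr(out, "montage") <- montage[montage$region == region, , drop = FALSE]
  out
}

#' Context/delay windowing configuration
#'
#' @param context_ms symmetric time-context length in ms; interpreted as an
#'   odd frame count at the 10 ms frame shift (0 -> 1 frame, 50 -> 5 frames,
#'   110 -> 11, 210 -> 21).
#' @param delay_ms delay tau in ms (multiple of 10); negative values shift
#'   the neural window into the past relative to the decoded frame.
#' @return an object of class `windowing_config`.
#' @export
windowing_config <- function(context_ms = 0, delay_ms = 0) {
  if (delay_ms %% 10 != 0) stop("delay must be a multiple of 10 ms")
  k <- floor(context_ms / 10 / 2)          # 210 -> +-10, 110 -> +-5, 50 -> +-2
  structure(list(context_ms = context_ms, delay_ms = delay_ms,
                 half_frames = as.integer(k),
                 delay_frames = as.integer(delay_ms / 10)),
            class = "windowing_config")
}

#' Concatenate temporal context and apply the neural-to-target delay
#'
#' Output frame t is the concatenation of neural frames
#' x(t + tau - k) ... x(t + tau + k) for a context of (2k+1) x 10 ms and delay
#' tau, aligned with target frame y(t). Frames whose window exits the sentence
#' use edge replication, so the output covers the full sentence.
#'
#' @param feat a `feature_track` at 100 Hz.
#' @param cfg a `windowing_config`.
#' @return a `feature_track` with dimension multiplied by (2k+1).
#' @export
window_features <- function(feat, cfg) {
  stopifnot(inherits(cfg, "windowing_config"))
  n <- nrow(feat)
  k <- cfg$half_frames
  if (2 * k + 1 > n) stop("context larger than sentence")
  if (abs(cfg$delay_frames) >= n) stop("delay larger than sentence")
  offs <- (-k):k + cfg$delay_frames
  mat <- unclass(feat)
  blocks <- lapply(offs, function(o) mat[clamp_idx(seq_len(n) + o, n), ,
                                         drop = FALSE])
  out <- do.call(cbind, blocks)
  labels <- unlist(lapply(offs, function(o)
    paste0(colnames(feat), "@", o * 10, "ms")))
  feature_track(out, rate = frame_rate(feat), labels = labels)
}
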