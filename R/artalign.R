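# Articulatory alignment: midsagittal projection of 3-D EMA, acoustic DTW
# features, resampling, dynamic time warping, and transfer of reference
# articulatory trajectories onto the patient's timing.
#
# The sample-wise DTW distance is a sum of squared differences over the 25
# normalized mel coefficients, the normalized F0 and the binary speech flag:
#   d(S1(t), S2(t)) = sum_m (c1^m - c2^m)^2 + (F01 - F02)^2
#                     + (speech1 - speech2)^2
# with each speaker's mel coefficients divided by that sentence's max |c_0|
# and F0 divided by its sentence maximum.

EMA_SENSORS_3D <- 9L      # upper/lower lip, 2 lip corners, tongue tip/back/
                          # dorsum, velum, jaw
EMA_FEATURES <- 14L       # 7 sensors x 2 midsagittal components

#' Project 3-D articulography onto the midsagittal plane
#'
#' Drops the two lip-corner sensors (they move mostly latero-medially), then
#' per remaining sensor centres the 3-D coordinates and projects them onto
#' their first two principal axes, giving 14 articulatory features.
#'
#' @param ema3d frames x 27 matrix (9 sensors x 3 coordinates, grouped by
#'   sensor) or `feature_track`.
#' @param lip_corner_sensors indices of the two lip-corner sensors (default
#'   c(3, 4)).
#' @return a `feature_track` (frames x 14) at the input rate.
#' @export
project_midsagittal <- function(ema3d, lip_corner_sensors = c(3L, 4L)) {
  rate <- if (inherits(ema3d, "feature_track")) frame_rate(ema3d) else 100
  m <- as.matrix(unclass(ema3d))
  if (ncol(m) != EMA_SENSORS_3D * 3L)
    stop("expected 9 sensors x 3 coordinates (27 columns)")
  keep <- setdiff(seq_len(EMA_SENSORS_3D), lip_corner_sensors)
  out <- matrix(0, nrow(m), length(keep) * 2L)
  labels <- character(length(keep) * 2L)
  for (i in seq_along(keep)) {
    s <- keep[i]
    xyz <- m[, (s - 1) * 3 + 1:3, drop = FALSE]
    xyz <- sweep(xyz, 2, colMeans(xyz))
    pc <- stats::prcomp(xyz, center = FALSE)
    out[, (i - 1) * 2 + 1:2] <- pc$x[, 1:2]
    labels[(i - 1) * 2 + 1:2] <- paste0("s", s, c("_pc1", "_pc2"))
  }
  feature_track(out, rate = rate, labels = labels)
}

#' Build the 27-dimensional acoustic DTW feature track for one sentence
#'
#' Mel coefficients are divided by the sentence's max |c_0|, F0 by its
#' sentence maximum (left untouched if fully unvoiced), and a 0/1 speech flag
#' from envelope-based detection is appended. Speech and voiced runs shorter
#' than 50 ms are zeroed.
#'
#' @param mel 25-column mel `feature_track` at 100 Hz.
#' @param f0 aligned F0 track (vector or one-column track), Hz.
#' @param speech 0/1 speech flag per frame (from [speech_flag()]), or a
#'   `speech_segments` object.
#' @return a `feature_track` (frames x 27).
#' @export
build_dtw_features <- function(mel, f0, speech) {
  f0 <- as.numeric(f0)
  n <- nrow(mel)
  if (n == 0 || length(f0) == 0) stop("empty tracks")
  if (length(f0) != n) stop("mel / F0 frame-count mismatch")
  if (inherits(speech, "speech_segments")) speech <- speech_flag(speech, n)
  speech <- as.numeric(speech)
  if (length(speech) != n) stop("speech flag frame-count mismatch")
  c0max <- max(abs(unclass(mel)[, 1]))
  meln <- unclass(mel) / c0max
  voiced <- drop_short_runs(f0 > 0, round(0.050 * FRAME_RATE))
  f0c <- ifelse(voiced, f0, 0)
  if (any(f0c > 0)) f0c <- f0c / max(f0c)
  sp <- as.numeric(drop_short_runs(speech > 0, round(0.050 * FRAME_RATE)))
  feature_track(cbind(meln, f0c, sp), rate = frame_rate(mel),
                labels = c(colnames(mel), "f0", "speech"))
}

#' Resample a feature track to a target number of frames
#'
#' Sides are padded by symmetric reflection before shape-preserving
#' piecewise-cubic interpolation onto `n` uniformly spaced points, which
#' suppresses edge overshoot; endpoints are preserved.
#'
#' @param track a `feature_track` (or matrix).
#' @param n target frame count (>= 2).
#' @return a `feature_track` with `n` frames.
#' @export
resample_to_length <- function(track, n) {
  if (n < 2) stop("target length must be >= 2")
  m <- as.matrix(unclass(track))
  len <- nrow(m)
  if (len < 2) stop("input track must have >= 2 frames")
  pad <- min(len - 1L, 8L)
  x <- seq_len(len + 2L * pad) - pad - 1L            # original grid 0..len-1
  xq <- seq(0, len - 1, length.out = n)
  out <- vapply(seq_len(ncol(m)), function(j)
    pchip_interp(x, sym_pad(m[, j], pad), xq), numeric(n))
  rate <- if (inherits(track, "feature_track")) frame_rate(track) else 100
  feature_track(out, rate = rate, labels = colnames(m))
}

#' Monotone warp path
#'
#' @param pairs two-column integer matrix of (reference, target) frame
#'   indices (1-based), starting at (1,1), ending at (n,m), steps in
#'   {(1,0),(0,1),(1,1)}.
#' @return an object of class `warp_path`.
#' @export
warp_path <- function(pairs) {
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  if (any(pairs[1, ] != 1L)) stop("warp path must start at (1,1)")
  d <- diff(pairs)
  if (nrow(pairs) > 1 &&
      (any(d < 0) || any(d[, 1] + d[, 2] == 0) || any(d > 1)))
    stop("warp path steps must be in {(1,0),(0,1),(1,1)}")
  colnames(pairs) <- c("ref", "target")
  structure(pairs, class = c("warp_path", "matrix", "array"))
}

#' @export
print.warp_path <- function(x, ...) {
  cat(sprintf("<warp_path> %d steps: (1,1) -> (%d,%d)\n",
              nrow(x), x[nrow(x), 1], x[nrow(x), 2]))
  invisible(x)
}

#' Dynamic time warping alignment of two feature tracks
#'
#' Dynamic-programming optimal monotone, boundary-anchored path under the
#' sample-wise sum-of-squares distance, with steps {(1,0),(0,1),(1,1)} and
#' ties broken in favour of the diagonal.
#'
#' @param ref reference DTW feature track (frames x d).
#' @param pat patient DTW feature track, same frame count (resample the
#'   reference with [resample_to_length()] first).
#' @param use_sqrt take the square root of the sample-wise distance
#'   (sensitivity check); default FALSE, the sum of squares as printed.
#' @return a `warp_path` with attribute `cost` (total path cost).
#' @export
dtw_align <- function(ref, pat, use_sqrt = FALSE) {
  A <- as.matrix(unclass(ref)); B <- as.matrix(unclass(pat))
  if (nrow(A) != nrow(B))
    stop("tracks must be resampled to the same length before DTW")
  if (ncol(A) != ncol(B)) stop("feature dimension mismatch")
  n <- nrow(A); m <- nrow(B)
  # local cost matrix: |a_i|^2 + |b_j|^2 - 2 a_i . b_j
  D <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  if (use_sqrt) D <- sqrt(D)
  # cumulative cost + backtracking (1 = diag, 2 = up/ref, 3 = left/target)
  G <- matrix(Inf, n, m)
  P <- matrix(0L, n, m)
  G[1, 1] <- D[1, 1]
  for (i in 2:n) { G[i, 1] <- G[i - 1, 1] + D[i, 1]; P[i, 1] <- 2L }
  for (j in 2:m) { G[1, j] <- G[1, j - 1] + D[1, j]; P[1, j] <- 3L }
  for (i in 2:n) {
    gim1 <- G[i - 1, ]
    gi <- G[i, ]
    for (j in 2:m) {
      diag <- gim1[j - 1]; up <- gim1[j]; left <- gi[j - 1]
      if (diag <= up && diag <= left) { gi[j] <- diag + D[i, j]; P[i, j] <- 1L }
      else if (up <= left)            { gi[j] <- up + D[i, j];   P[i, j] <- 2L }
      else                            { gi[j] <- left + D[i, j]; P[i, j] <- 3L }
    }
    G[i, ] <- gi
  }
  # backtrack
  path <- matrix(0L, n + m, 2)
  i <- n; j <- m; k <- n + m
  repeat {
    path[k, ] <- c(i, j)
    if (i == 1 && j == 1) break
    s <- P[i, j]
    if (s == 1L) { i <- i - 1L; j <- j - 1L }
    else if (s == 2L) i <- i - 1L
    else j <- j - 1L
    k <- k - 1L
  }
  wp <- warp_path(path[k:(n + m), , drop = FALSE])
  attr(wp, "cost") <- G[n, m]
  wp
}

#' Transfer reference articulation through a warp path
#'
#' For each patient frame j, the estimated articulatory frame is the mean of
#' the reference frames paired with j in the path (or the last match).
#'
#' @param path a `warp_path`.
#' @param ref_ema reference articulatory `feature_track` whose frame count
#'   matches the path's reference range.
#' @param target_len number of patient frames (defaults to the path's target
#'   range).
#' @param aggregate "mean" (default) or "last".
#' @return an estimated articulatory `feature_track` with `target_len` frames.
#' @export
transfer_articulation <- function(path, ref_ema, target_len = NULL,
                                  aggregate = c("mean", "last")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(path, "warp_path"))
  m <- as.matrix(unclass(ref_ema))
  n_ref <- path[nrow(path), 1]
  n_tgt <- path[nrow(path), 2]
  if (is.null(target_len)) target_len <- n_tgt
  if (nrow(m) != n_ref)
    stop("reference track length does not match the warp path")
  if (target_len != n_tgt)
    stop("target length does not match the warp path")
  out <- matrix(0, target_len, ncol(m))
  refs <- split(path[, 1], path[, 2])
  for (j in seq_len(target_len)) {
    ii <- refs[[as.character(j)]]
    out[j, ] <- if (aggregate == "mean" && length(ii) > 1)
      colMeans(m[ii, , drop = FALSE]) else m[ii[length(ii)], ]
  }
  rate <- if (inherits(ref_ema, "feature_track")) frame_rate(ref_ema) else 100
  feature_track(out, rate = rate, labels = colnames(m))
}

#' Estimate a patient sentence's articulatory trajectories
#'
#' Full transfer for one sentence pair: builds the 27-dimensional DTW feature
#' tracks for both speakers, resamples the reference to the patient length,
#' aligns by DTW, and warps the reference articulation through the path.
#'
#' @param ref_mel,ref_f0,ref_speech,ref_ema reference sentence tracks.
#' @param pat_mel,pat_f0,pat_speech patient sentence tracks.
#' @param use_sqrt passed to [dtw_align()].
#' @return list with `ema` (estimated patient articulation), `path` (the
#'   `warp_path` in resampled-reference index space) and `ref_warped_mel`
#'   (reference mel warped onto the patient timing, used as the evaluation
#'   reference for non-fine-tuned indirect decoding).
#' @export
estimate_patient_ema <- function(ref_mel, ref_f0, ref_speech, ref_ema,
                                 pat_mel, pat_f0, pat_speech,
                                 use_sqrt = FALSE) {
  fr <- build_dtw_features(ref_mel, ref_f0, ref_speech)
  fp <- build_dtw_features(pat_mel, pat_f0, pat_speech)
  npat <- nrow(fp)
  fr_rs <- resample_to_length(fr, npat)
  ema_rs <- resample_to_length(ref_ema, npat)
  mel_rs <- resample_to_length(ref_mel, npat)
  wp <- dtw_align(fr_rs, fp, use_sqrt = use_sqrt)
  list(ema = transfer_articulation(wp, ema_rs, npat),
       path = wp,
       ref_warped_mel = transfer_articulation(wp, mel_rs, npat))
}
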