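#' Feature track: frames x features matrix at a fixed frame rate
#'
#' The common container for all frame-synchronous features in the pipeline:
#' mel-cepstral coefficients, F0, articulatory (EMA) coordinates, neural band
#' powers. Rows are frames (100 Hz by convention), columns are labelled
#' features.
#'
#' @param data numeric matrix (frames x features) or a vector (one feature).
#' @param rate frame rate in Hz (default 100).
#' @param labels optional character vector of feature labels.
#' @return An object of class `feature_track` (a matrix with `rate` attribute).
#' @export
feature_track <- function(data, rate = 100, labels = NULL) {
  if (is.null(dim(data))) data <- matrix(data, ncol = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("feature_track: non-finite values")
  if (!is.numeric(rate) || rate <= 0) stop("feature_track: rate must be > 0")
  if (!is.null(labels)) {
    if (length(labels) != ncol(data))
      stop("feature_track: labels length != number of features")
    colnames(data) <- labels
  } else if (is.null(colnames(data))) {
    colnames(data) <- paste0("f", seq_len(ncol(data)))
  }
  structure(data, rate = rate, class = c("feature_track", "matrix", "array"))
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("<feature_track> %d frames x %d features @ %g Hz (%.2f s)\n",
              nrow(x), ncol(x), attr(x, "rate"), nrow(x) / attr(x, "rate")))
  invisible(x)
}

#' Frame rate of a feature track
#' @param x a `feature_track`
#' @return frame rate in Hz
#' @export
frame_rate <- function(x) attr(x, "rate")

#' Number of frames
#' @param x a `feature_track`
#' @return frame count
#' @export
n_frames <- function(x) nrow(x)

# strip class but keep the data (for matrix algebra)
as_matrix <- function(x) {
  attr(x, "rate") <- NULL
  class(x) <- NULL
  dim(x) <- dim(x)  # keep
  x
}

#' Audio waveform
#'
#' @param samples numeric amplitude vector.
#' @param rate sampling rate in Hz.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("waveform: non-finite samples")
  if (rate <= 0) stop("waveform: rate must be > 0")
  structure(list(samples = samples, rate = rate), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.2f s), peak %.3f\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              max(abs(x$samples))))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a `waveform`
#' @return duration in seconds
#' @export
wav_duration <- function(w) length(w$samples) / w$rate

#' One utterance: id, text, condition, waveform and feature tracks
#'
#' @param id sentence identifier.
#' @param text sentence text.
#' @param condition speaking condition label (e.g. "read", "repeat").
#' @param audio a `waveform` (or NULL).
#' @param tracks named list of `feature_track`s (e.g. mel, f0, ema, neural).
#' @param speaker speaker tag (e.g. "reference", "patient").
#' @return An object of class `sentence_record`.
#' @export
sentence_record <- function(id, text = "", condition = "read", audio = NULL,
                            tracks = list(), speaker = "reference") {
  structure(list(id = id, text = text, condition = condition, audio = audio,
                 tracks = tracks, speaker = speaker),
            class = "sentence_record")
}

#' @export
print.sentence_record <- function(x, ...) {
  cat(sprintf("<sentence_record> id=%s speaker=%s condition=%s tracks: %s\n",
              x$id, x$speaker, x$condition,
              paste(names(x$tracks), collapse = ", ")))
  invisible(x)
}
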