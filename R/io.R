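# File input/output: WAV audio, delimited feature-track tables, sentence
# manifests, warp paths and decoder archives.

#' Write a mono waveform to a RIFF/WAV file
#'
#' 16-bit PCM (default) or 32-bit IEEE float. Samples outside [-1, 1] are
#' clipped for the 16-bit encoding.
#'
#' @param w a `waveform`.
#' @param path output file path.
#' @param bits 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bits = 16) {
  stopifnot(inherits(w, "waveform"), bits %in% c(16, 32))
  n <- length(w$samples)
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per <- bits / 8
  data_len <- n * bytes_per
  fmt <- if (bits == 16) 1L else 3L   # PCM vs IEEE float
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (bits == 16) {
    s <- pmin(pmax(w$samples, -1), 1)
    writeBin(as.integer(round(s * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(w$samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono RIFF/WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float, as written by [write_wav()].
#'
#' @param path WAV file path.
#' @return a `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; rate <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    len <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      nch <- readBin(con, integer(), size = 2, endian = "little")
      if (nch != 1) stop("only mono WAV supported")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (len > 16) invisible(readBin(con, raw(), n = len - 16))
    } else if (id == "data") {
      if (bits == 16) {
        s <- readBin(con, integer(), n = len / 2, size = 2,
                     endian = "little", signed = TRUE) / 32767
      } else if (bits == 32 && fmt == 3) {
        s <- readBin(con, numeric(), n = len / 4, size = 4, endian = "little")
      } else stop("unsupported WAV encoding")
      return(waveform(s, rate))
    } else {
      invisible(readBin(con, raw(), n = len))
    }
  }
}

#' Write a feature track as a delimited numeric table
#'
#' Tab-separated, header row with feature labels; a `# rate: <Hz>` comment
#' line records the frame rate.
#'
#' @param track a `feature_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate: %g", frame_rate(track)), con)
  utils::write.table(as.data.frame(unclass(track)[, , drop = FALSE]), con,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature track written by [write_track()]
#' @param path input path.
#' @return a `feature_track`.
#' @export
read_track <- function(path) {
  first <- readLines(path, n = 1)
  rate <- if (grepl("^# rate:", first)) as.numeric(sub("^# rate:", "", first)) else 100
  dat <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE)
  feature_track(as.matrix(dat), rate = rate, labels = colnames(dat))
}

#' Write a corpus to a directory
#'
#' One WAV per sentence, one delimited table per feature track per sentence,
#' and a manifest table (id, text, condition, speaker, duration).
#'
#' @param corpus list of `sentence_record`s.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(id = character(), text = character(),
                    condition = character(), speaker = character(),
                    duration = numeric())
  for (s in corpus) {
    if (!is.null(s$audio))
      write_wav(s$audio, file.path(dir, paste0(s$id, ".wav")))
    for (nm in names(s$tracks))
      write_track(s$tracks[[nm]], file.path(dir, paste0(s$id, "_", nm, ".tsv")))
    dur <- if (!is.null(s$audio)) wav_duration(s$audio) else
      n_frames(s$tracks[[1]]) / frame_rate(s$tracks[[1]])
    man <- rbind(man, data.frame(id = s$id, text = s$text,
                                 condition = s$condition, speaker = s$speaker,
                                 duration = dur))
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#' @param dir corpus directory.
#' @return list of `sentence_record`s.
#' @export
read_corpus <- function(dir) {
  man <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                           sep = "\t")
  lapply(seq_len(nrow(man)), function(i) {
    id <- man$id[i]
    wavp <- file.path(dir, paste0(id, ".wav"))
    audio <- if (file.exists(wavp)) read_wav(wavp) else NULL
    tfiles <- list.files(dir, pattern = paste0("^", id, "_.*\\.tsv$"),
                         full.names = TRUE)
    tracks <- stats::setNames(
      lapply(tfiles, read_track),
      sub("\\.tsv$", "", sub(paste0("^", id, "_"), "", basename(tfiles))))
    sentence_record(id, man$text[i], man$condition[i], audio, tracks,
                    man$speaker[i])
  })
}

#' Serialize a warp path as a two-column index table
#' @param path_obj a `warp_path`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_warp <- function(path_obj, file) {
  utils::write.table(data.frame(ref = path_obj[, 1], target = path_obj[, 2]),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a warp path written by [write_warp()]
#' @param file input path.
#' @return a `warp_path`.
#' @export
read_warp <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t")
  warp_path(cbind(d$ref, d$target))
}

#' Save a fitted decoder (weights, preprocessing state, configuration)
#'
#' Single-file archive with a format version field.
#'
#' @param model a `decoder_model`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
save_decoder <- function(model, file) {
  stopifnot(inherits(model, "decoder_model"))
  model$format_version <- 1L
  saveRDS(model, file)
  invisible(file)
}

#' Load a decoder archive written by [save_decoder()]
#' @param file archive path.
#' @return a `decoder_model`.
#' @export
load_decoder <- function(file) {
  m <- readRDS(file)
  if (is.null(m$format_version)) stop("not a decoder archive")
  class(m) <- "decoder_model"
  m
}
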