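# File I/O: WAV audio, Audacity-style label tracks, long-format rating
# tables, and acoustic profile tables. WAV support is a minimal RIFF
# reader/writer for mono/stereo PCM16 and IEEE float32, which covers every
# file the pipeline produces or consumes.

#' Write a WAV file
#'
#' @param samples Numeric vector (mono) or matrix with one column per
#'   channel, values nominally in [-1, 1].
#' @param path Output path.
#' @param sample_rate Sample rate in Hz.
#' @param bit_depth 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate, bit_depth = 16) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stopifnot(is.numeric(samples), bit_depth %in% c(16, 32))
  n_ch <- ncol(samples)
  n <- nrow(samples)
  interleaved <- as.numeric(t(samples))
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per_sample <- bit_depth / 8
  data_size <- n * n_ch * bytes_per_sample
  fmt <- if (bit_depth == 16) 1L else 3L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_ch * bytes_per_sample), con,
           size = 4, endian = "little")
  writeBin(as.integer(n_ch * bytes_per_sample), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16) {
    x <- as.integer(round(clip(interleaved, -1, 1) * 32767))
    writeBin(x, con, size = 2, endian = "little")
  } else {
    writeBin(interleaved, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Reads mono or multi-channel PCM16 or float32 RIFF/WAVE files.
#'
#' @param path Path to a WAV file.
#' @return List with `samples` (numeric matrix, one column per channel,
#'   in [-1, 1] for PCM) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, raw(), n = size)
      fmt <- list(
        format = sum(as.integer(fmt_raw[1:2]) * c(1, 256)),
        n_ch = sum(as.integer(fmt_raw[3:4]) * c(1, 256)),
        rate = sum(as.integer(fmt_raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(fmt_raw[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      n_samp <- size / (fmt$bits / 8)
      if (fmt$format == 1 && fmt$bits == 16) {
        x <- readBin(con, integer(), n = n_samp, size = 2,
                     signed = TRUE, endian = "little") / 32767
      } else if (fmt$format == 3 && fmt$bits == 32) {
        x <- readBin(con, numeric(), n = n_samp, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ",
             fmt$bits, " bit) in ", path)
      }
      samples <- matrix(x, ncol = fmt$n_ch, byrow = TRUE)
      return(list(samples = samples, sample_rate = fmt$rate))
    } else {
      invisible(readBin(con, raw(), n = size + size %% 2))
    }
  }
}

#' Write a note-boundary label track
#'
#' Audacity-style tab-separated label track: `start_s<TAB>end_s<TAB>label`,
#' one row per note, labels being 0-based note indices.
#'
#' @param labels Data frame with columns `start_s`, `end_s`, `note_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("start_s", "end_s", "note_index") %in% names(labels)))
  utils::write.table(
    data.frame(start_s = sprintf("%.6f", labels$start_s),
               end_s = sprintf("%.6f", labels$end_s),
               note_index = labels$note_index),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a note-boundary label track
#'
#' @param path Path to a tab-separated label track.
#' @return Data frame with columns `start_s`, `end_s`, `note_index`.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("start_s", "end_s", "note_index"),
                          colClasses = c("numeric", "numeric", "integer"))
  if (any(is.na(df$start_s)) || any(is.na(df$end_s))) {
    bad <- which(is.na(df$start_s) | is.na(df$end_s))[1]
    stop("malformed label track row ", bad, " in ", path)
  }
  df
}

#' Write / read a long-format rating table
#'
#' Long format: one row per (participant, stimulus, scale) with columns
#' `participant_id`, `stimulus_id`, `scale`, `value` and optionally
#' `normalized_value`, `is_repeat`, `block`, `presentation_order` plus
#' design columns (`singer_id`, `melody`, `take`).
#'
#' @param ratings Rating data frame.
#' @param path CSV path.
#' @return `path` invisibly (writer); the data frame (reader).
#' @export
write_ratings <- function(ratings, path) {
  stopifnot(all(c("participant_id", "stimulus_id", "scale", "value") %in%
                  names(ratings)))
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "stimulus_id", "scale", "value")
  if (!all(req %in% names(df))) {
    stop("ratings file missing required columns: ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  if (any(!is.finite(df$value))) {
    stop("non-numeric rating value at row ", which(!is.finite(df$value))[1])
  }
  bad <- df$value != round(df$value)
  if (any(bad)) {
    stop("non-integer rating value at row ", which(bad)[1])
  }
  if ("is_repeat" %in% names(df)) df$is_repeat <- as.logical(df$is_repeat)
  df
}

#' Write / read an acoustic profile table
#'
#' One row per stimulus with the full per-performance feature vector;
#' column order is stable across runs.
#'
#' @param profiles Data frame of acoustic profiles (see [extract_profile()]).
#' @param path CSV path.
#' @return `path` invisibly (writer); the data frame (reader).
#' @export
write_profiles <- function(profiles, path) {
  cols <- intersect(profile_column_order(), names(profiles))
  utils::write.csv(profiles[, c(cols, setdiff(names(profiles), cols))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

profile_column_order <- function() {
  c("stimulus_id", "singer_id", "melody", "take",
    "pitch_interval_deviation", "vibrato_rate", "vibrato_extent",
    "energy_ratio", "jitter_local", "shimmer_local", "hnr35", "cpp",
    "h1_h2", "h1_a1", "h1_a2", "h1_a3",
    "tempo_s_per_beat", "bpm", "mean_f0", "loudness_lufs")
}
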