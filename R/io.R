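## Readers and writers for the pipeline's plain-text artifacts, plus
## minimal PCM16 WAV support (no audio package ships with the target
## environment).

required_annotation_cols <- c("tag_id", "call_id", "start_s", "end_s",
                              "category", "quality")

#' Read a call annotation table
#'
#' Validates the schema (required columns, end >= start, unique call
#' ids, per-tag start-time monotonicity after sorting) and returns calls
#' sorted by start time within tag. Violations are reported with the
#' offending row numbers of the input file.
#'
#' @param path CSV path with columns tag_id, call_id, start_s, end_s,
#'   category, quality and optionally snr_db, low_snr_override.
#' @return Data.frame of calls.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_annotation_cols, names(df))
  if (length(missing))
    abort(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
          "orcaseq_load_error")
  bad <- which(df$end_s < df$start_s)
  if (length(bad))
    abort(sprintf("end_s < start_s on row(s): %s",
                  paste(bad, collapse = ", ")), "orcaseq_load_error")
  dup <- which(duplicated(df$call_id))
  if (length(dup))
    abort(sprintf("duplicated call_id on row(s): %s",
                  paste(dup, collapse = ", ")), "orcaseq_load_error")
  nonnum <- !vapply(df[c("start_s", "end_s")], is.numeric, logical(1))
  if (any(nonnum))
    abort("start_s/end_s must be numeric", "orcaseq_load_error")
  df <- df[order(df$tag_id, df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a tail-slap event table
#'
#' @param path CSV with columns tag_id, time_s and optionally quality.
#' @return Data.frame of slap events sorted by time within tag.
#' @export
read_tail_slaps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("tag_id", "time_s"), names(df))
  if (length(missing))
    abort(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
          "orcaseq_load_error")
  df <- df[order(df$tag_id, df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read an Audacity label track
#'
#' Tab-separated `start \t end \t label` rows as exported by Audacity's
#' label tracks.
#'
#' @param path Label-track text file.
#' @return Data.frame start_s, end_s, label.
#' @export
read_audacity_labels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    abort("label track needs 3 tab-separated columns", "orcaseq_load_error")
  stats::setNames(df[, 1:3], c("start_s", "end_s", "label"))
}

#' Write / read a transition table as long-format CSV
#'
#' @param table A `transition_table`.
#' @param path Output CSV (columns from, to, count).
#' @export
write_transition_counts <- function(table, path) {
  counts <- table$counts
  long <- data.frame(from = rep(rownames(counts), ncol(counts)),
                     to = rep(colnames(counts), each = nrow(counts)),
                     count = as.vector(counts), stringsAsFactors = FALSE)
  long <- long[long$count > 0, , drop = FALSE]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition_counts
#' @param path CSV written by [write_transition_counts()].
#' @return A count matrix.
#' @export
read_transition_counts <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  cats <- sort(unique(c(long$from, long$to)))
  m <- matrix(0L, length(cats), length(cats),
              dimnames = list(from = cats, to = cats))
  m[cbind(match(long$from, cats), match(long$to, cats))] <-
    as.integer(long$count)
  m
}

#' Minimal PCM16 mono WAV writer / reader
#'
#' @param wave Numeric samples in [-1, 1] after normalization by
#'   `scale`; clipped beyond.
#' @param path Output path.
#' @param sample_rate Sampling rate (Hz).
#' @param scale Full-scale amplitude mapped to 16-bit maximum.
#' @export
write_wav <- function(wave, path, sample_rate, scale = max(abs(wave), 1)) {
  x <- as.integer(round(pmax(-1, pmin(1, wave / scale)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_data <- 2L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_data), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_data, con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @return For `read_wav`: list `wave` (numeric in [-1, 1]),
#'   `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort("not a RIFF file", "orcaseq_load_error")
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE"))
    abort("not a WAVE file", "orcaseq_load_error")
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4)
      abort("no data chunk found", "orcaseq_load_error")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        abort("only PCM mono supported", "orcaseq_load_error")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, raw(), n = sz - 8L)
    } else if (id == "data") {
      x <- readBin(con, integer(), n = sz / 2L, size = 2, signed = TRUE,
                   endian = "little")
      return(list(wave = x / 32767, sample_rate = sample_rate))
    } else readBin(con, raw(), n = sz)
  }
}

#' Write a synthetic tag to CSV files
#'
#' Emits the annotation table, tail-slap table and truth sidecar for one
#' or more tags under a common prefix.
#'
#' @param dataset Output of [generate_dataset()] (or a single
#'   `synthetic_tag`).
#' @param dir Output directory (created if needed).
#' @return Invisible named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  if (inherits(dataset, "synthetic_tag"))
    dataset <- list(calls = dataset$calls, tail_slaps = dataset$tail_slaps,
                    truth = cbind(tag_id = dataset$tag_id, dataset$truth))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(calls = file.path(dir, "calls.csv"),
             tail_slaps = file.path(dir, "tail_slaps.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(dataset$calls, paths["calls"], row.names = FALSE)
  utils::write.csv(dataset$tail_slaps, paths["tail_slaps"], row.names = FALSE)
  utils::write.csv(dataset$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
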