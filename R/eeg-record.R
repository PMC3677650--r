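#' Construct an EEG record
#'
#' An `eeg_record` is a tibble with one numeric column per channel plus
#' metadata attributes: the sampling rate, the seizure-onset time (seconds
#' from the start of the record) and a record identifier. It is the common
#' carrier for recorded and simulated EEG throughout the package.
#'
#' @param data A data frame with one numeric column per channel and one row
#'   per sample (row order is time order).
#' @param sampling_rate_hz Sampling rate in Hz; must be positive. Invasive
#'   presurgical monitoring data of the kind this package targets is
#'   typically sampled at 256 Hz.
#' @param seizure_onset_s Seizure onset in seconds from the start of the
#'   record, or `NULL` if unknown. Must not exceed the record duration.
#' @param record_id Identifier string (e.g. a patient/seizure key).
#'
#' @return A tibble of class `eeg_record`.
#' @examples
#' rec <- eeg_record(data.frame(ch1 = rnorm(512)), 256, seizure_onset_s = 2)
#' sampling_rate(rec)
#' @export
eeg_record <- function(data, sampling_rate_hz, seizure_onset_s = NULL,
                       record_id = "record") {
  data <- tibble::as_tibble(data)
  if (nrow(data) < 1L) {
    stop("empty input: an EEG record needs at least one sample", call. = FALSE)
  }
  if (!all(vapply(data, is.numeric, logical(1)))) {
    stop("all channels must be numeric", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a single positive number", call. = FALSE)
  }
  duration_s <- nrow(data) / sampling_rate_hz
  if (!is.null(seizure_onset_s)) {
    if (!is.numeric(seizure_onset_s) || length(seizure_onset_s) != 1L ||
        seizure_onset_s < 0) {
      stop("`seizure_onset_s` must be a single non-negative number",
           call. = FALSE)
    }
    if (seizure_onset_s > duration_s + 1e-9) {
      stop(sprintf(
        "`seizure_onset_s` (%.3f s) exceeds the record duration (%.3f s)",
        seizure_onset_s, duration_s), call. = FALSE)
    }
  }
  tibble::new_tibble(
    data,
    sampling_rate_hz = sampling_rate_hz,
    seizure_onset_s = seizure_onset_s,
    record_id = as.character(record_id),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "<eeg_record '%s': %d channel(s) x %d samples @ %g Hz (%.2f min)%s>\n",
    record_id(x), ncol(x), nrow(x), sampling_rate(x),
    nrow(x) / sampling_rate(x) / 60,
    if (is.null(seizure_onset(x))) "" else
      sprintf(", onset %.1f s", seizure_onset(x))))
  NextMethod()
}

#' Metadata accessors for EEG records and segments
#'
#' @param x An `eeg_record` or `eeg_segment`.
#' @return `sampling_rate()` the sampling rate in Hz, `seizure_onset()` the
#'   onset time in seconds from record start (or `NULL`), `record_id()` the
#'   identifier string.
#' @export
sampling_rate <- function(x) attr(x, "sampling_rate_hz", exact = TRUE)

#' @rdname sampling_rate
#' @export
seizure_onset <- function(x) attr(x, "seizure_onset_s", exact = TRUE)

#' @rdname sampling_rate
#' @export
record_id <- function(x) attr(x, "record_id", exact = TRUE)

detect_delim <- function(line) {
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  "whitespace"
}

split_fields <- function(lines, delim) {
  if (identical(delim, "whitespace")) {
    strsplit(trimws(lines), "[ \t]+")
  } else {
    lapply(strsplit(lines, delim, fixed = TRUE), trimws)
  }
}

#' Read an EEG record from delimited text
#'
#' Reads a plain-text EEG export with one sample per row and one channel per
#' column. The delimiter (whitespace, comma or tab) is auto-detected from the
#' first line unless given. Row order is taken as time order.
#'
#' @param path Path to the text file.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param seizure_onset_s Seizure onset in seconds from record start, or
#'   `NULL`.
#' @param record_id Identifier; defaults to the file name without extension.
#' @param channel_labels Optional character vector of channel names; defaults
#'   to `ch1`, `ch2`, ...
#' @param delim Delimiter: `","`, `"\t"`, `"whitespace"`, or `NULL` to
#'   auto-detect.
#'
#' @return An [eeg_record].
#' @seealso [write_eeg_text()], [read_eeg_int16()]
#' @export
read_eeg_text <- function(path, sampling_rate_hz, seizure_onset_s = NULL,
                          record_id = NULL, channel_labels = NULL,
                          delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) == 0L) {
    stop("empty input: no data rows in ", path, call. = FALSE)
  }
  if (is.null(delim)) delim <- detect_delim(lines[[1L]])
  fields <- split_fields(lines, delim)
  ncols <- lengths(fields)
  if (any(ncols != ncols[[1L]])) {
    bad <- which(ncols != ncols[[1L]])[[1L]]
    stop(sprintf(
      "format error: row %d has %d fields, expected %d (ragged rows)",
      bad, ncols[[bad]], ncols[[1L]]), call. = FALSE)
  }
  nc <- ncols[[1L]]
  raw <- unlist(fields, use.names = FALSE)
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    idx <- which(is.na(vals))[[1L]]
    stop(sprintf(
      "parse error: non-numeric value '%s' at row %d, column %d",
      raw[[idx]], (idx - 1L) %/% nc + 1L, (idx - 1L) %% nc + 1L),
      call. = FALSE)
  }
  mat <- matrix(vals, ncol = nc, byrow = TRUE)
  labels <- channel_labels %||% paste0("ch", seq_len(nc))
  if (length(labels) != nc) {
    stop("`channel_labels` length does not match the column count",
         call. = FALSE)
  }
  colnames(mat) <- labels
  if (is.null(record_id)) {
    record_id <- sub("\\.[^.]*$", "", basename(path))
  }
  eeg_record(as.data.frame(mat), sampling_rate_hz, seizure_onset_s, record_id)
}

#' Write an EEG record as delimited text
#'
#' Writes one sample per row and one channel per column, with no header, in
#' the format [read_eeg_text()] reads back.
#'
#' @param record An [eeg_record] or `eeg_segment`.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_eeg_text <- function(record, path, delim = "\t") {
  df <- as.data.frame(record)
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an EEG record from flat 16-bit integer binary
#'
#' Decodes the channel-interleaved signed 16-bit layout used by raw EEG
#' exports from digital acquisition systems with 16-bit A/D conversion
#' (sample 1 of channels 1..k, then sample 2 of channels 1..k, ...).
#'
#' @inheritParams read_eeg_text
#' @param n_channels Number of interleaved channels (>= 1).
#' @param byte_order `"little"` or `"big"`.
#' @param scale Multiplicative calibration from ADC counts to voltage units
#'   (default 1, i.e. raw counts).
#' @return An [eeg_record] with `size / (2 * n_channels)` samples per channel.
#' @export
read_eeg_int16 <- function(path, n_channels, sampling_rate_hz,
                           seizure_onset_s = NULL, record_id = NULL,
                           channel_labels = NULL,
                           byte_order = c("little", "big"), scale = 1) {
  byte_order <- match.arg(byte_order)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!is.numeric(n_channels) || n_channels < 1 || n_channels %% 1 != 0) {
    stop("`n_channels` must be a positive integer", call. = FALSE)
  }
  n_channels <- as.integer(n_channels)
  size <- file.size(path)
  if (size %% (2L * n_channels) != 0) {
    stop(sprintf(
      "truncation error: file size %d bytes is not divisible by 2 x %d channels",
      size, n_channels), call. = FALSE)
  }
  n <- size %/% (2L * n_channels)
  v <- readBin(path, "integer", n = n * n_channels, size = 2L,
               signed = TRUE, endian = byte_order)
  mat <- matrix(as.numeric(v) * scale, ncol = n_channels, byrow = TRUE)
  colnames(mat) <- channel_labels %||% paste0("ch", seq_len(n_channels))
  if (is.null(record_id)) record_id <- sub("\\.[^.]*$", "", basename(path))
  eeg_record(as.data.frame(mat), sampling_rate_hz, seizure_onset_s, record_id)
}

#' Extract a single-channel preictal segment
#'
#' Cuts the interval from `start_min` to `end_min` minutes before seizure
#' onset out of one channel. The segment covers the half-open interval
#' `[onset - start_min * 60, onset - end_min * 60)` seconds so that tiled
#' segments never double-count a sample, and its timestamps are re-expressed
#' relative to onset (negative = preictal).
#'
#' @param record An [eeg_record] with a known seizure onset.
#' @param channel Channel name or index. Which channel overlies the
#'   epileptogenic focus is recording-specific metadata and must be supplied
#'   by the caller.
#' @param start_min Minutes before onset at which the segment starts
#'   (default 32).
#' @param end_min Minutes before onset at which the segment ends (default 4;
#'   use 0 to run up to onset).
#'
#' @return A tibble of class `eeg_segment` with columns `t_s` (seconds
#'   relative to onset) and `value`, carrying the sampling rate, record id
#'   and channel as attributes.
#' @export
extract_preictal <- function(record, channel, start_min = 32, end_min = 4) {
  if (!inherits(record, "eeg_record")) {
    stop("`record` must be an eeg_record", call. = FALSE)
  }
  if (!(is.numeric(start_min) && is.numeric(end_min) &&
        start_min > end_min && end_min >= 0)) {
    stop("need `start_min` > `end_min` >= 0 (minutes before onset)",
         call. = FALSE)
  }
  onset <- seizure_onset(record)
  if (is.null(onset)) {
    stop("record has no seizure onset time", call. = FALSE)
  }
  if (is.character(channel) && !channel %in% colnames(record)) {
    stop(sprintf("channel '%s' not found (channels: %s)", channel,
                 paste(colnames(record), collapse = ", ")), call. = FALSE)
  }
  if (is.numeric(channel) && (channel < 1 || channel > ncol(record))) {
    stop("channel index out of range", call. = FALSE)
  }
  rate <- sampling_rate(record)
  seg_start_s <- onset - start_min * 60
  if (seg_start_s < -1e-9) {
    stop(sprintf(
      "insufficient history: the window needs %.1f s before onset but only %.1f s are recorded (shortfall %.1f s)",
      start_min * 60, onset, -seg_start_s), call. = FALSE)
  }
  n_out <- floor((start_min - end_min) * 60 * rate)
  first <- floor(rate * seg_start_s) + 1L
  last <- first + n_out - 1L
  if (last > nrow(record)) {
    stop("segment extends past the end of the record", call. = FALSE)
  }
  x <- record[[channel]][first:last]
  t_s <- (seq.int(first, last) - 1L) / rate - onset
  label <- if (is.character(channel)) channel else colnames(record)[[channel]]
  tibble::new_tibble(
    tibble::tibble(t_s = t_s, value = x),
    sampling_rate_hz = rate,
    record_id = record_id(record),
    channel = label,
    start_min = start_min,
    end_min = end_min,
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf(
    "<eeg_segment '%s' channel %s: [%g, %g) min rel. onset, %d samples @ %g Hz>\n",
    record_id(x), attr(x, "channel"), -attr(x, "start_min"),
    -attr(x, "end_min"), nrow(x), sampling_rate(x)))
  NextMethod()
}
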