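#' OpenBCI GUI text dialect
#'
#' Describes the raw text layout written by the OpenBCI GUI for a Cyton+Daisy
#' board: '%'-prefixed header lines, a comma-separated column-name line, then
#' one comma-separated row per sample (sample index, EXG channels, auxiliary
#' columns, timestamp).
#'
#' @param header_prefix Comment marker prefixing metadata lines.
#' @param eeg_pattern Regex selecting the EEG columns by name.
#' @param timestamp_col Name of the absolute-timestamp column (ms since epoch).
#' @param sep Field separator.
#' @return A list of class `openbci_dialect`.
#' @export
openbci_dialect <- function(header_prefix = "%", eeg_pattern = "^EXG Channel",
                            timestamp_col = "Timestamp", sep = ",") {
  structure(list(header_prefix = header_prefix, eeg_pattern = eeg_pattern,
                 timestamp_col = timestamp_col, sep = sep),
            class = "openbci_dialect")
}

#' Parse a raw OpenBCI text recording
#'
#' Reads the GUI's text export, keeps only the EEG columns (in file order),
#' drops and counts malformed rows, and returns an [eeg_recording()] in
#' microvolts. The recording's start time is the first valid row's timestamp;
#' sample times are `start_time + index / fs` (per-row logger timestamps
#' jitter and are not used beyond the first).
#'
#' @param path Path to the text file.
#' @param fs Sampling rate in Hz.
#' @param dialect An [openbci_dialect()].
#' @return An `eeg_recording` with the dropped-row count in its history.
#' @export
parse_openbci_txt <- function(path, fs = 125, dialect = openbci_dialect()) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_header <- startsWith(lines, dialect$header_prefix)
  body <- lines[!is_header & nzchar(trimws(lines))]
  if (length(body) < 2L) abort(sprintf("No data rows in %s", path))
  cols <- trimws(strsplit(body[[1]], dialect$sep, fixed = TRUE)[[1]])
  eeg_idx <- grep(dialect$eeg_pattern, cols)
  if (!length(eeg_idx))
    abort(sprintf("No columns matching '%s' in %s", dialect$eeg_pattern, path))
  ts_idx <- match(dialect$timestamp_col, cols)
  if (is.na(ts_idx))
    abort(sprintf("Timestamp column '%s' not found in %s",
                  dialect$timestamp_col, path))
  fields <- strsplit(body[-1L], dialect$sep, fixed = TRUE)
  ok_len <- lengths(fields) == length(cols)
  vals <- matrix(NA_real_, nrow = sum(ok_len), ncol = length(cols))
  if (any(ok_len)) {
    flat <- suppressWarnings(as.numeric(unlist(fields[ok_len], use.names = FALSE)))
    vals <- matrix(flat, ncol = length(cols), byrow = TRUE)
  }
  ok_num <- !apply(is.na(vals[, c(eeg_idx, ts_idx), drop = FALSE]), 1, any)
  n_dropped <- sum(!ok_len) + sum(!ok_num)
  vals <- vals[ok_num, , drop = FALSE]
  if (nrow(vals) == 0L)
    abort(sprintf("No valid data rows in %s (%d dropped)", path, n_dropped))
  rec <- eeg_recording(t(vals[, eeg_idx, drop = FALSE]), fs = fs,
                       channel_labels = cols[eeg_idx],
                       start_time = vals[1L, ts_idx])
  annotate_recording(rec, "ingest", source = path, n_rows = nrow(vals),
                     n_dropped_rows = n_dropped)
}

#' Write / read a recording as standardized CSV
#'
#' The CSV has one header row (channel labels plus `timestamp`) and one row per
#' sample; timestamps are reconstructed as `start_time + index / fs` in ms.
#' Reading back reproduces the data within float-text precision.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @return `write_recording_csv()` returns `path` invisibly;
#'   `read_recording_csv()` returns an `eeg_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  df$timestamp <- rec$start_time +
    (seq_len(n_samples(rec)) - 1L) / rec$fs * 1000
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) abort(sprintf("Cannot write CSV to %s: %s",
                                      path, conditionMessage(e))))
  invisible(path)
}

#' @rdname write_recording_csv
#' @param fs Sampling rate; if `NULL`, inferred from the timestamp column.
#' @export
read_recording_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"timestamp" %in% names(df))
    abort(sprintf("No 'timestamp' column in %s", path))
  ts <- df$timestamp
  if (is.null(fs)) fs <- 1000 / stats::median(diff(ts))
  dat <- as.matrix(df[setdiff(names(df), "timestamp")])
  eeg_recording(t(dat), fs = fs, channel_labels = colnames(dat),
                start_time = ts[1L])
}

#' Session metadata
#'
#' Participant and condition identifiers plus the gameplay interval and
#' mini-game entries that drive trimming and segmentation. Timestamps are
#' absolute milliseconds since epoch; `buffer_s` widens the gameplay interval
#' on both sides to cover preparatory and post-task activity.
#'
#' @param participant_id Participant identifier string.
#' @param condition `"GT"` (still baseline) or `"MVMT"` (full-body movement).
#' @param gameplay_start,gameplay_end Gameplay interval (ms since epoch).
#' @param buffer_s Non-negative symmetric buffer in seconds (default 2).
#' @param minigames List of entries `list(label=, index=, start=, end=,
#'   adjustment_s=)`; `adjustment_s` is a signed per-mini-game shift in
#'   seconds (default 0) accommodating domain-specific timing offsets.
#' @return A list of class `session_meta`.
#' @export
session_meta <- function(participant_id, condition, gameplay_start,
                         gameplay_end, buffer_s = 2, minigames = list()) {
  condition <- match.arg(condition, c("GT", "MVMT"))
  if (!(gameplay_start < gameplay_end))
    abort("`gameplay_start` must precede `gameplay_end`.")
  if (buffer_s < 0) abort("`buffer_s` must be non-negative.")
  minigames <- lapply(minigames, function(m) {
    m$adjustment_s <- m$adjustment_s %||% 0
    stopifnot(!is.null(m$label), !is.null(m$index), m$index >= 1,
              !is.null(m$start), !is.null(m$end), m$start < m$end)
    m
  })
  structure(list(participant_id = participant_id, condition = condition,
                 gameplay_start = gameplay_start, gameplay_end = gameplay_end,
                 buffer_s = buffer_s, minigames = minigames),
            class = "session_meta")
}

#' @rdname session_meta
#' @param path JSON file path.
#' @export
read_session_meta <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  session_meta(j$participant_id, j$condition, j$gameplay_start,
               j$gameplay_end, j$buffer_s %||% 2,
               j$minigames %||% list())
}

#' @rdname session_meta
#' @param meta A `session_meta`.
#' @export
write_session_meta <- function(meta, path) {
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Trim a recording to the buffered gameplay interval
#'
#' Keeps the samples inside `[gameplay_start - buffer_s, gameplay_end +
#' buffer_s)` intersected with the recording; intervals are half-open in
#' seconds relative to the recording start, with 0-based sample indexing.
#' Trimming an already-trimmed recording with the same metadata is the
#' identity.
#'
#' @param rec An `eeg_recording`.
#' @param meta A [session_meta()].
#' @return The trimmed recording; trimmed durations are logged in its history.
#' @export
trim_to_gameplay <- function(rec, meta) {
  fs <- rec$fs
  n <- n_samples(rec)
  rel_start <- (meta$gameplay_start - rec$start_time) / 1000 - meta$buffer_s
  rel_end <- (meta$gameplay_end - rec$start_time) / 1000 + meta$buffer_s
  i0 <- floor(rel_start * fs)
  i1 <- floor(rel_end * fs)
  if (i1 <= 0 || i0 >= n)
    abort(sprintf(
      "Gameplay interval [%.2f, %.2f] s does not overlap recording [0, %.2f] s.",
      rel_start, rel_end, n / fs))
  clipped <- i0 < 0 || i1 > n
  if (i1 > n)
    warn(sprintf("Gameplay interval extends %.2f s past recording end; clipped.",
                 (i1 - n) / fs))
  i0 <- max(0L, i0)
  i1 <- min(n, i1)
  out <- subset_samples(rec, (i0 + 1L):i1)
  out$start_time <- rec$start_time + i0 / fs * 1000
  annotate_recording(out, "trim",
                     trimmed_head_s = i0 / fs,
                     trimmed_tail_s = (n - i1) / fs,
                     clipped = clipped)
}

#' Segment a trimmed recording into per-mini-game recordings
#'
#' Cuts one recording per mini-game entry, shifting each interval by its
#' `adjustment_s`. Labels follow `"{condition}/{participant}/{label}_{index}"`.
#' Mini-games falling fully outside the recording are skipped with a warning.
#' Overlapping mini-game intervals are allowed and segmented independently.
#'
#' @param rec A trimmed `eeg_recording`.
#' @param meta A [session_meta()].
#' @return A tibble with columns `label`, `start_s`, `end_s` (relative to the
#'   recording) and a `recording` list-column.
#' @export
segment_minigames <- function(rec, meta) {
  fs <- rec$fs
  n <- n_samples(rec)
  rows <- purrr::map(meta$minigames, function(m) {
    s <- (m$start - rec$start_time) / 1000 + m$adjustment_s
    e <- (m$end - rec$start_time) / 1000 + m$adjustment_s
    i0 <- max(0L, floor(s * fs))
    i1 <- min(n, floor(e * fs))
    label <- sprintf("%s/%s/%s_%d", meta$condition, meta$participant_id,
                     m$label, m$index)
    if (i1 <= i0) {
      warn(sprintf("Mini-game '%s' lies outside the recording; skipped.", label))
      return(NULL)
    }
    seg <- subset_samples(rec, (i0 + 1L):i1)
    seg$start_time <- rec$start_time + i0 / fs * 1000
    seg <- annotate_recording(seg, "segment", label = label,
                              adjustment_s = m$adjustment_s)
    tibble(label = label, start_s = i0 / fs, end_s = i1 / fs,
           recording = list(seg))
  })
  dplyr::bind_rows(rows)
}
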