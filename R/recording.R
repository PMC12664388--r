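#' Multichannel EEG recording
#'
#' The container every pipeline stage transforms: a channels-by-samples numeric
#' matrix in microvolts, plus the sampling rate, unique channel labels, the
#' absolute start time, and an ordered provenance history of stage annotations.
#'
#' @param data Numeric matrix, `n_channels x n_samples`, in microvolts.
#' @param fs Sampling rate in Hz (the hardware default is 125).
#' @param channel_labels Character vector of unique labels, one per row of
#'   `data`. Defaults to `"EXG Channel 0"` ... style labels.
#' @param start_time Absolute start time in milliseconds since epoch.
#' @param history List of stage annotations (see [annotate_recording()]).
#'
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(32), nrow = 2), fs = 125)
#' n_channels(rec)
#' duration_s(rec)
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL, start_time = 0,
                          history = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    abort("`data` must be a numeric matrix (channels x samples).")
  if (anyNA(data)) abort("`data` must not contain missing values.")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    abort("`fs` must be a single positive number (Hz).")
  if (nrow(data) < 1L) abort("A recording needs at least one channel.")
  if (is.null(channel_labels))
    channel_labels <- sprintf("EXG Channel %d", seq_len(nrow(data)) - 1L)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    abort("`channel_labels` must have one entry per channel.")
  if (anyDuplicated(channel_labels))
    abort("`channel_labels` must be unique.")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = as.numeric(fs), channel_labels = channel_labels,
         start_time = as.numeric(start_time), history = history),
    class = "eeg_recording"
  )
}

#' @rdname eeg_recording
#' @param x,rec An `eeg_recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname eeg_recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname eeg_recording
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Append a provenance annotation to a recording's history
#'
#' @param rec An `eeg_recording`.
#' @param stage Short stage name (e.g. `"ingest"`, `"asr"`).
#' @param ... Named details recorded with the annotation.
#' @return The recording with the annotation appended.
#' @export
annotate_recording <- function(rec, stage, ...) {
  rec$history <- c(rec$history, list(c(list(stage = stage), list(...))))
  rec
}

# Keep a subset of samples (logical mask or integer index), preserving order.
subset_samples <- function(rec, keep) {
  rec$data <- rec$data[, keep, drop = FALSE]
  rec
}

# Keep a subset of channels by label or index.
subset_channels <- function(rec, keep) {
  data <- rec$data[keep, , drop = FALSE]
  eeg_recording(data, rec$fs, rownames(data), rec$start_time, rec$history)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              n_channels(x), n_samples(x), x$fs, duration_s(x)))
  cat("channels:", paste(head(x$channel_labels, 6), collapse = ", "),
      if (n_channels(x) > 6) "..." else "", "\n")
  if (length(x$history)) {
    stages <- vapply(x$history, function(h) h$stage, character(1))
    cat("history:", paste(stages, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Convert a recording to a long tibble
#'
#' One row per (time, channel) pair, suitable for dplyr/ggplot2 work.
#'
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `channel`, `value_uv`.
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  tibble(
    time_s = rep((seq_len(n_samples(x)) - 1L) / x$fs, each = n_channels(x)),
    channel = rep(x$channel_labels, times = n_samples(x)),
    value_uv = as.vector(x$data)
  )
}

#' Plot a recording as stacked channel traces
#'
#' @param object An `eeg_recording`.
#' @param max_points Per-channel cap on plotted samples (decimated above it).
#' @param spacing_uv Vertical offset between traces; defaults to 4x the median
#'   channel standard deviation.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_recording <- function(object, max_points = 4000,
                                   spacing_uv = NULL, ...) {
  dec <- max(1L, floor(n_samples(object) / max_points))
  idx <- seq(1L, n_samples(object), by = dec)
  if (is.null(spacing_uv))
    spacing_uv <- 4 * stats::median(apply(object$data, 1, sd)) + 1e-9
  k <- n_channels(object)
  df <- tibble(
    time_s = rep((idx - 1L) / object$fs, times = k),
    channel = factor(rep(object$channel_labels, each = length(idx)),
                     levels = rev(object$channel_labels)),
    value = as.vector(t(object$data[, idx, drop = FALSE])) +
      rep((k - seq_len(k)) * spacing_uv, each = length(idx))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value,
                                   group = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::scale_y_continuous(
      breaks = (k - seq_len(k)) * spacing_uv,
      labels = object$channel_labels) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
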