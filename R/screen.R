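#' Channel-screening configuration
#'
#' Thresholds for the four bad-channel criteria applied before ASR:
#' high-impedance (extreme mean amplitude, indicating poor electrode contact),
#' flatline, low correlation to the robust signal mean, and z-score amplitude
#' outliers.
#'
#' @param impedance_threshold_uv Mean-amplitude threshold in microvolts; a
#'   channel is flagged when its mean amplitude strictly exceeds it
#'   (default 48000).
#' @param impedance_stat `"mean_abs"` (default) flags on the mean absolute
#'   amplitude so large symmetric artifacts cannot cancel; `"mean"` uses the
#'   signed mean.
#' @param flatline_min_s Minimum flat-run duration in seconds (default 5).
#' @param flatline_var_tol Variance tolerance in uV^2 treating digitally
#'   constant segments with float noise as flat (default 1e-10).
#' @param corr_threshold Minimum Pearson correlation with the leave-one-out
#'   cross-channel median reference (default 0.85).
#' @param z_threshold Robust z-score bound on per-channel standard deviation
#'   (default 4).
#' @param min_channels Minimum surviving channels for the session to continue
#'   (default 4; ICA needs several channels).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(impedance_threshold_uv = 48000,
                          impedance_stat = c("mean_abs", "mean"),
                          flatline_min_s = 5, flatline_var_tol = 1e-10,
                          corr_threshold = 0.85, z_threshold = 4,
                          min_channels = 4) {
  impedance_stat <- match.arg(impedance_stat)
  stopifnot(impedance_threshold_uv > 0, flatline_min_s > 0,
            flatline_var_tol > 0, corr_threshold > 0, corr_threshold <= 1,
            z_threshold > 0, min_channels >= 1)
  structure(list(impedance_threshold_uv = impedance_threshold_uv,
                 impedance_stat = impedance_stat,
                 flatline_min_s = flatline_min_s,
                 flatline_var_tol = flatline_var_tol,
                 corr_threshold = corr_threshold, z_threshold = z_threshold,
                 min_channels = min_channels),
            class = "screen_config")
}

verdict_tbl <- function(labels, reason, value, flagged) {
  tibble(channel = labels, reason = reason, value = value, flagged = flagged)
}

#' Bad-channel detectors
#'
#' Each detector evaluates one criterion on every channel and returns a
#' verdict tibble with the measured statistic. [screen_channels()] combines
#' them in the pipeline's two-step order.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [screen_config()].
#' @return A tibble with columns `channel`, `reason`, `value`, `flagged`.
#' @name detectors
NULL

#' @describeIn detectors Flags channels whose mean (absolute) amplitude
#'   strictly exceeds `impedance_threshold_uv`.
#' @export
detect_high_impedance <- function(rec, cfg = screen_config()) {
  stat <- if (cfg$impedance_stat == "mean_abs")
    rowMeans(abs(rec$data)) else abs(rowMeans(rec$data))
  verdict_tbl(rec$channel_labels, "high_impedance", unname(stat),
              unname(stat) > cfg$impedance_threshold_uv)
}

#' @describeIn detectors Flags channels with a contiguous run of duration
#'   `>= flatline_min_s` whose variance is within `flatline_var_tol`. The run
#'   search treats consecutive samples differing by less than
#'   `sqrt(flatline_var_tol)` as constant.
#' @export
detect_flatline <- function(rec, cfg = screen_config()) {
  min_run <- cfg$flatline_min_s * rec$fs
  if (n_samples(rec) < min_run) {
    warn(sprintf("Recording shorter than %g s; flatline criterion skipped.",
                 cfg$flatline_min_s))
    return(verdict_tbl(rec$channel_labels, "flatline", NA_real_, FALSE))
  }
  eps <- sqrt(cfg$flatline_var_tol)
  runs <- apply(rec$data, 1, function(x) {
    flat <- abs(diff(x)) <= eps
    r <- rle(flat)
    m <- r$lengths[r$values]
    if (length(m)) (max(m) + 1L) / rec$fs else 1 / rec$fs
  })
  verdict_tbl(rec$channel_labels, "flatline", unname(runs),
              unname(runs) >= cfg$flatline_min_s)
}

#' @describeIn detectors Flags channels whose Pearson correlation with the
#'   per-sample cross-channel median of the *other* channels (leave-one-out
#'   robust reference) falls below `corr_threshold`.
#' @export
detect_low_correlation <- function(rec, cfg = screen_config()) {
  if (n_channels(rec) < 3L) {
    warn("Fewer than 3 channels; low-correlation criterion skipped.")
    return(verdict_tbl(rec$channel_labels, "low_correlation", NA_real_, FALSE))
  }
  rs <- vapply(seq_len(n_channels(rec)), function(i) {
    ref <- apply(rec$data[-i, , drop = FALSE], 2, median)
    if (sd(ref) == 0 || sd(rec$data[i, ]) == 0) return(0)
    cor(rec$data[i, ], ref)
  }, numeric(1))
  verdict_tbl(rec$channel_labels, "low_correlation", rs,
              rs < cfg$corr_threshold)
}

#' @describeIn detectors Flags channels whose amplitude (standard deviation
#'   over time) is a robust z-score outlier: `|amp - median| / (1.4826 * MAD)`
#'   strictly above `z_threshold`.
#' @export
detect_noisy <- function(rec, cfg = screen_config()) {
  if (n_channels(rec) < 3L) {
    warn("Fewer than 3 channels; noisy-channel criterion skipped.")
    return(verdict_tbl(rec$channel_labels, "noisy", NA_real_, FALSE))
  }
  amp <- apply(rec$data, 1, sd)
  madv <- mad(amp)  # 1.4826 scaling built in
  if (madv == 0) {
    warn("Zero MAD of channel amplitudes; noisy-channel criterion skipped.")
    return(verdict_tbl(rec$channel_labels, "noisy", rep(0, length(amp)), FALSE))
  }
  z <- (amp - median(amp)) / madv
  verdict_tbl(rec$channel_labels, "noisy", unname(z),
              abs(unname(z)) > cfg$z_threshold)
}

#' Screen and remove bad channels
#'
#' Two-step screening: high-impedance channels are removed first, then the
#' flatline, low-correlation and noisy criteria are evaluated on the surviving
#' set (their statistics therefore never see the extreme-amplitude channels).
#' If fewer than `min_channels` channels survive, the session is marked
#' excluded rather than erroring.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [screen_config()].
#' @return A list of class `channel_screen` with elements `recording` (bad
#'   channels removed), `verdicts` (per-channel summary tibble: `channel`,
#'   `removed`, `reasons`), `details` (long per-criterion tibble), `status`
#'   (`"ok"` or `"excluded"`), and the retention counts after each step.
#' @export
screen_channels <- function(rec, cfg = screen_config()) {
  imp <- detect_high_impedance(rec, cfg)
  surv1 <- rec$channel_labels[!imp$flagged]
  rec1 <- subset_channels(rec, !imp$flagged)
  details <- imp
  if (n_channels(rec1) > 0) {
    details <- dplyr::bind_rows(
      details,
      detect_flatline(rec1, cfg),
      detect_low_correlation(rec1, cfg),
      detect_noisy(rec1, cfg))
  }
  summary <- details |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      removed = any(.data$flagged),
      reasons = list(.data$reason[.data$flagged]), .groups = "drop") |>
    dplyr::arrange(match(.data$channel, rec$channel_labels))
  keep <- summary$channel[!summary$removed]
  out <- subset_channels(rec, match(keep, rec$channel_labels))
  status <- if (n_channels(out) < cfg$min_channels) "excluded" else "ok"
  out <- annotate_recording(out, "screen",
                            n_removed = n_channels(rec) - n_channels(out),
                            removed = summary$channel[summary$removed],
                            status = status)
  structure(list(recording = out, verdicts = summary, details = details,
                 status = status,
                 n_original = n_channels(rec),
                 n_after_impedance = length(surv1),
                 n_retained = n_channels(out)),
            class = "channel_screen")
}

#' @export
print.channel_screen <- function(x, ...) {
  cat(sprintf("<channel_screen> %d/%d channels retained (%s)\n",
              x$n_retained, x$n_original, x$status))
  bad <- dplyr::filter(x$verdicts, .data$removed)
  if (nrow(bad))
    cat(paste(sprintf(" - %s: %s", bad$channel,
                      vapply(bad$reasons, paste, "", collapse = ", ")),
              collapse = "\n"), "\n")
  invisible(x)
}

#' @export
tidy.channel_screen <- function(x, ...) x$details

#' @export
glance.channel_screen <- function(x, ...) {
  tibble(n_original = x$n_original,
         n_after_impedance = x$n_after_impedance,
         n_retained = x$n_retained,
         retention_pct = 100 * x$n_retained / x$n_original,
         status = x$status)
}

#' @export
autoplot.channel_screen <- function(object, ...) {
  df <- dplyr::filter(object$details, !is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$channel, .data$value,
                                   fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~reason, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "criterion statistic") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
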