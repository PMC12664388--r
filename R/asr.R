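#' ASR configuration
#'
#' Parameters of Artifact Subspace Reconstruction, named after the EEGLAB
#' convention: `channel_criterion` and `line_noise_criterion` are pre-ASR
#' channel checks on the calibration data (largely redundant after channel
#' screening but honored for parameter fidelity and logged when they fire),
#' `burst_criterion` sets detection aggressiveness in calibration standard
#' deviations, and `window_criterion` is the tolerated fraction of components
#' still exceeding their bounds before a window is dropped outright.
#'
#' @param channel_criterion Minimum correlation with the robust channel
#'   average on calibration data (default 0.85).
#' @param line_noise_criterion Robust z bound on relative line-noise power
#'   (default 4).
#' @param burst_criterion Number of calibration standard deviations above the
#'   mean windowed component RMS that triggers reconstruction (default 3).
#' @param window_criterion Maximum fraction of components allowed to exceed
#'   their thresholds after correction (default 0.05).
#' @param calib_window_s Window length in seconds for clean-reference
#'   selection (default 1).
#' @param detect_window_s Detection window length in seconds (default 0.5).
#' @param detect_overlap Fractional overlap between detection windows
#'   (default 0.5).
#' @param ref_z_bounds Per-channel robust-z bounds a window must satisfy to
#'   enter the clean reference (default `c(-3.5, 5)`).
#' @param line_freq Mains frequency in Hz for the line-noise check
#'   (default 50).
#' @return A list of class `asr_config`.
#' @export
asr_config <- function(channel_criterion = 0.85, line_noise_criterion = 4,
                       burst_criterion = 3, window_criterion = 0.05,
                       calib_window_s = 1, detect_window_s = 0.5,
                       detect_overlap = 0.5, ref_z_bounds = c(-3.5, 5),
                       line_freq = 50) {
  stopifnot(burst_criterion > 0, window_criterion > 0, window_criterion < 1,
            calib_window_s > 0, detect_window_s > 0,
            detect_overlap >= 0, detect_overlap < 1,
            length(ref_z_bounds) == 2, ref_z_bounds[1] < ref_z_bounds[2])
  structure(list(channel_criterion = channel_criterion,
                 line_noise_criterion = line_noise_criterion,
                 burst_criterion = burst_criterion,
                 window_criterion = window_criterion,
                 calib_window_s = calib_window_s,
                 detect_window_s = detect_window_s,
                 detect_overlap = detect_overlap,
                 ref_z_bounds = ref_z_bounds, line_freq = line_freq),
            class = "asr_config")
}

# Window start indices (0-based) covering n samples with length L and hop h;
# the final window is anchored to the end so coverage is complete.
window_starts <- function(n, L, h) {
  if (n <= L) return(0L)
  s <- seq(0L, n - L, by = h)
  if (tail(s, 1) < n - L) s <- c(s, n - L)
  s
}

#' Select the clean calibration reference
#'
#' Splits the recording into `calib_window_s` windows, computes each channel's
#' RMS per window, robust-z-scores the RMS across windows per channel, and
#' marks a window clean when every channel's z lies within `ref_z_bounds`.
#' The clean fraction varies by session and is reported for the cleaning log.
#'
#' Channels failing `channel_criterion` (correlation with the cross-channel
#' median) or `line_noise_criterion` (robust z of relative power near
#' `line_freq`) on the calibration data are logged in the result; they are
#' expected to have been removed during channel screening.
#'
#' @param rec An `eeg_recording`.
#' @param cfg An [asr_config()].
#' @return A list of class `asr_reference`: `mask` (per-sample logical),
#'   `clean_fraction`, `window_clean` (per-window logical), and
#'   `channel_flags` (tibble of pre-check warnings).
#' @export
find_clean_reference <- function(rec, cfg = asr_config()) {
  X <- rec$data
  if (all(apply(X, 1, sd) < 1e-12))
    abort(paste("Calibration failed: recording has zero variance.",
                "Relax thresholds or inspect the input."))
  fs <- rec$fs
  n <- n_samples(rec)
  L <- max(2L, round(cfg$calib_window_s * fs))
  starts <- window_starts(n, L, L)
  rms <- vapply(starts, function(s) {
    w <- X[, (s + 1L):(s + L), drop = FALSE]
    sqrt(rowMeans(w^2))
  }, numeric(nrow(X)))
  rms <- matrix(rms, nrow = nrow(X))  # channels x windows
  z <- t(apply(rms, 1, function(r) {
    m <- mad(r)
    if (m == 0) rep(0, length(r)) else (r - median(r)) / m
  }))
  wclean <- apply(z >= cfg$ref_z_bounds[1] & z <= cfg$ref_z_bounds[2], 2, all)
  if (!any(wclean))
    abort(paste("No calibration window qualifies as clean.",
                "Relax `ref_z_bounds` or shorten `calib_window_s`."))
  mask <- rep(FALSE, n)
  for (i in seq_along(starts))
    if (wclean[i]) mask[(starts[i] + 1L):(starts[i] + L)] <- TRUE
  # trailing samples not covered by a full window inherit the last verdict
  covered <- max(starts) + L
  if (covered < n) mask[(covered + 1L):n] <- wclean[length(wclean)]

  flags <- asr_channel_precheck(rec, cfg)
  if (nrow(flags))
    warn(sprintf("ASR pre-check flagged channels: %s",
                 paste(flags$channel, collapse = ", ")))
  structure(list(mask = mask, clean_fraction = mean(mask),
                 window_clean = wclean, channel_flags = flags),
            class = "asr_reference")
}

# ChannelCriterion / LineNoiseCriterion checks, logged but not removing.
asr_channel_precheck <- function(rec, cfg) {
  X <- rec$data
  k <- nrow(X)
  out <- list()
  if (k >= 3) {
    rs <- vapply(seq_len(k), function(i) {
      ref <- apply(X[-i, , drop = FALSE], 2, median)
      if (sd(ref) == 0 || sd(X[i, ]) == 0) 0 else cor(X[i, ], ref)
    }, numeric(1))
    bad <- rs < cfg$channel_criterion
    out$corr <- tibble(channel = rec$channel_labels[bad],
                       check = "channel_criterion", value = rs[bad])
    lin <- vapply(seq_len(k), function(i) {
      p <- welch_psd(X[i, ], rec$fs)
      band <- p$freq >= cfg$line_freq - 1 & p$freq <= cfg$line_freq + 1
      sum(p$psd[band]) / sum(p$psd)
    }, numeric(1))
    # floor the spread so near-zero line power across the board never flags
    zl <- (lin - median(lin)) / max(mad(lin), 0.01)
    badl <- zl > cfg$line_noise_criterion
    out$line <- tibble(channel = rec$channel_labels[badl],
                       check = "line_noise_criterion", value = zl[badl])
  }
  dplyr::bind_rows(out) %||% tibble(channel = character(), check = character(),
                                    value = numeric())
}

#' Calibrate ASR on the clean reference
#'
#' Builds the statistical model of clean EEG: principal components of the
#' masked-data covariance, a square-root mixing estimate, and a per-component
#' RMS bound `mean + burst_criterion * sd` of the windowed component RMS over
#' the calibration data (windows of `detect_window_s`, matching detection).
#'
#' @param rec An `eeg_recording` (channel-screened, unfiltered).
#' @param mask Per-sample logical clean mask from [find_clean_reference()],
#'   or an `asr_reference`.
#' @param cfg An [asr_config()].
#' @return A list of class `asr_state`: eigenbasis `V`, mixing estimate `M`
#'   (symmetric PSD square root of the calibration covariance), per-component
#'   `thresholds`, per-channel `means`, and channel metadata.
#' @export
calibrate_asr <- function(rec, mask, cfg = asr_config()) {
  if (inherits(mask, "asr_reference")) mask <- mask$mask
  fs <- rec$fs
  if (sum(mask) < 5 * fs)
    abort("Calibration mask must cover at least 5 s of data.")
  X <- rec$data[, mask, drop = FALSE]
  means <- rowMeans(X)
  Xc <- X - means
  C <- Xc %*% t(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  if (any(vals < 1e-12 * max(vals)))
    warn("Rank-deficient calibration covariance; proceeding with pseudo-inverse.")
  V <- eg$vectors
  M <- V %*% (sqrt(vals) * t(V))
  L <- max(2L, round(cfg$detect_window_s * fs))
  starts <- window_starts(ncol(Xc), L, L)
  S <- t(V) %*% Xc
  rms <- vapply(starts, function(s)
    sqrt(rowMeans(S[, (s + 1L):(s + L), drop = FALSE]^2)),
    numeric(nrow(S)))
  rms <- matrix(rms, nrow = nrow(S))
  thresholds <- rowMeans(rms) + cfg$burst_criterion * apply(rms, 1, sd)
  # null-space components carry no signal; never trigger on their float noise
  thresholds[vals < 1e-9 * max(vals)] <- Inf
  structure(list(V = V, M = M, eigenvalues = vals, thresholds = thresholds,
                 means = means, calibration_mask = mask,
                 channel_labels = rec$channel_labels, fs = fs),
            class = "asr_state")
}

#' Apply ASR reconstruction
#'
#' Slides `detect_window_s` windows (with `detect_overlap`) over the
#' recording; in each window the data are projected onto the calibration
#' eigenbasis and components whose RMS exceeds their calibrated bound are
#' reconstructed from the retained subspace via the calibration mixing
#' estimate. Corrected windows are blended with raised-cosine weights at the
#' seams. Windows with no exceeding component pass through identically, so a
#' clean recording is returned (numerically) unchanged.
#'
#' @param rec An `eeg_recording` on the same channel set as `state`.
#' @param state An [calibrate_asr()] result.
#' @param cfg An [asr_config()].
#' @return A list of class `asr_result`: `recording` (corrected),
#'   `reconstructed` (per-sample logical mask of modified windows), and
#'   `reconstructed_fraction`.
#' @export
apply_asr <- function(rec, state, cfg = asr_config()) {
  if (!identical(rec$channel_labels, state$channel_labels))
    abort("Channel set differs from the calibrated ASR state.")
  fs <- rec$fs
  n <- n_samples(rec)
  k <- n_channels(rec)
  L <- max(2L, round(cfg$detect_window_s * fs))
  h <- max(1L, round(L * (1 - cfg$detect_overlap)))
  starts <- window_starts(n, L, h)
  Xc <- rec$data - state$means
  Tm <- t(state$V)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = L)) + 1e-3
  Y <- matrix(0, k, n)
  Wacc <- rep(0, n)
  modified <- rep(FALSE, n)
  for (s in starts) {
    idx <- (s + 1L):(s + L)
    Xw <- Xc[, idx, drop = FALSE]
    comp_rms <- sqrt(rowMeans((Tm %*% Xw)^2))
    bad <- comp_rms > state$thresholds
    if (any(bad)) {
      signal <- state$eigenvalues >= 1e-9 * max(state$eigenvalues)
      if (!any(signal & !bad)) {
        # no clean signal direction left: suppress the window outright
        # (window rejection will usually drop it afterwards)
        Xw <- Xw * 0
      } else {
        Tk <- Tm
        Tk[bad | !signal, ] <- 0
        R <- state$M %*% MASS::ginv(Tk %*% state$M) %*% Tk
        Xw <- R %*% Xw
      }
      modified[idx] <- TRUE
    }
    Y[, idx] <- Y[, idx] + Xw * rep(w, each = k)
    Wacc[idx] <- Wacc[idx] + w
  }
  Y <- Y / rep(Wacc, each = k) + state$means
  out <- rec
  out$data <- Y
  out <- annotate_recording(out, "asr",
                            reconstructed_fraction = mean(modified),
                            burst_criterion = cfg$burst_criterion)
  structure(list(recording = out, reconstructed = modified,
                 reconstructed_fraction = mean(modified)),
            class = "asr_result")
}

#' Reject windows with pervasive residual noise
#'
#' After reconstruction, windows in which the fraction of calibration
#' components still exceeding their RMS bounds is greater than
#' `window_criterion` are removed from the time axis (the component basis has
#' one component per channel, so this is the per-channel accounting in the
#' calibration frame). Dropping everything marks the session excluded.
#'
#' @param rec The corrected `eeg_recording` from [apply_asr()].
#' @param state The `asr_state` used for correction.
#' @param cfg An [asr_config()].
#' @return A list: `recording` (samples in dropped windows removed), `dropped`
#'   (tibble of dropped intervals in seconds), `status`.
#' @export
reject_bad_windows <- function(rec, state, cfg = asr_config()) {
  if (!identical(rec$channel_labels, state$channel_labels))
    abort("Channel set differs from the calibrated ASR state.")
  fs <- rec$fs
  n <- n_samples(rec)
  L <- max(2L, round(cfg$detect_window_s * fs))
  starts <- window_starts(n, L, L)
  Xc <- rec$data - state$means
  Tm <- t(state$V)
  drop_mask <- rep(FALSE, n)
  dropped <- list()
  for (s in starts) {
    idx <- (s + 1L):(s + L)
    comp_rms <- sqrt(rowMeans((Tm %*% Xc[, idx, drop = FALSE])^2))
    frac <- mean(comp_rms > state$thresholds)
    if (frac > cfg$window_criterion) {
      drop_mask[idx] <- TRUE
      dropped[[length(dropped) + 1L]] <-
        tibble(start_s = s / fs, end_s = (s + L) / fs, frac_exceeding = frac)
    }
  }
  dropped <- dplyr::bind_rows(dropped) %||%
    tibble(start_s = numeric(), end_s = numeric(), frac_exceeding = numeric())
  status <- if (all(drop_mask)) "excluded" else "ok"
  out <- subset_samples(rec, !drop_mask)
  out <- annotate_recording(out, "asr_window_rejection",
                            dropped_s = sum(drop_mask) / fs, status = status)
  list(recording = out, dropped = dropped, status = status)
}

#' @export
print.asr_state <- function(x, ...) {
  cat(sprintf("<asr_state> %d channels, thresholds [%.3g, %.3g] uV RMS, %.1f s calibration\n",
              length(x$channel_labels), min(x$thresholds), max(x$thresholds),
              sum(x$calibration_mask) / x$fs))
  invisible(x)
}
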