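#' High-pass filter specification
#'
#' Zero-phase Hamming-window FIR high-pass with a duration-adaptive cutoff:
#' shorter sessions use 0.5 Hz (preserving slow dynamics when few cycles fit
#' in the recording), longer sessions 1.0 Hz. The order is fixed at 208,
#' balancing transition sharpness against edge effects at 125 Hz.
#'
#' @param cutoff_short_hz Cutoff for sessions shorter than
#'   `duration_threshold_s` (default 0.5 Hz).
#' @param cutoff_long_hz Cutoff for longer sessions (default 1.0 Hz).
#' @param order Even filter order (default 208; kernel length `order + 1`).
#' @param duration_threshold_s Session-length boundary in seconds between the
#'   two cutoffs (default 120; durations at the boundary use the long cutoff).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_short_hz = 0.5, cutoff_long_hz = 1.0,
                        order = 208, duration_threshold_s = 120) {
  stopifnot(order %% 2 == 0, order > 0, cutoff_short_hz > 0,
            cutoff_long_hz > 0, duration_threshold_s > 0)
  structure(list(cutoff_short_hz = cutoff_short_hz,
                 cutoff_long_hz = cutoff_long_hz, order = order,
                 duration_threshold_s = duration_threshold_s),
            class = "filter_spec")
}

#' Choose the duration-adaptive cutoff
#'
#' @param dur_s Session duration in seconds.
#' @param spec A [filter_spec()].
#' @return The cutoff in Hz: the short cutoff below the duration threshold,
#'   the long cutoff at or above it.
#' @export
choose_cutoff <- function(dur_s, spec = filter_spec()) {
  stopifnot(dur_s > 0)
  if (dur_s < spec$duration_threshold_s) spec$cutoff_short_hz
  else spec$cutoff_long_hz
}

#' Design the zero-phase high-pass kernel
#'
#' Spectral inversion of a unit-DC-gain Hamming-windowed sinc low-pass: the
#' coefficients are symmetric (exactly linear phase) and sum to zero, so DC is
#' nulled exactly while the passband stays within a fraction of a percent of
#' unity.
#'
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Cutoff frequency; must be below Nyquist.
#' @param spec A [filter_spec()] (supplies the order).
#' @return Numeric coefficient vector of length `order + 1`.
#' @export
design_highpass <- function(fs, cutoff_hz, spec = filter_spec()) {
  if (cutoff_hz >= fs / 2)
    abort(sprintf("Cutoff %g Hz is not below Nyquist (%g Hz).", cutoff_hz, fs / 2))
  order <- spec$order
  m <- order / 2
  n <- 0:order
  lp <- ifelse(n == m, 2 * cutoff_hz / fs,
               sin(pi * 2 * cutoff_hz / fs * (n - m)) / (pi * (n - m)))
  w <- 0.54 - 0.46 * cos(2 * pi * n / order)
  lp <- lp * w
  lp <- lp / sum(lp)          # exact unit DC gain before inversion
  hp <- -lp
  hp[m + 1] <- hp[m + 1] + 1  # delta minus low-pass
  hp
}

#' Apply a symmetric FIR kernel with zero phase
#'
#' Centered convolution with the symmetric kernel (exactly linear phase, group
#' delay compensated) and reflection padding at the edges, so the output has
#' the input's length and no phase shift at any frequency.
#'
#' @param rec An `eeg_recording` longer than the filter order.
#' @param coeffs Odd-length symmetric coefficient vector from
#'   [design_highpass()].
#' @return The filtered recording.
#' @export
apply_zero_phase <- function(rec, coeffs) {
  ord <- length(coeffs) - 1L
  n <- n_samples(rec)
  if (n <= ord)
    abort(sprintf(
      "Recording (%d samples) must be longer than the filter order (%d); use a lower order.",
      n, ord))
  half <- ord / 2
  filt1 <- function(x) {
    xp <- c(rev(x[2:(ord + 1)]), x, rev(x[(n - ord):(n - 1)]))
    y <- stats::filter(xp, coeffs, sides = 2)
    as.numeric(y[(ord + 1L):(ord + n)])
  }
  out <- rec
  out$data <- t(apply(rec$data, 1, filt1))
  rownames(out$data) <- rec$channel_labels
  annotate_recording(out, "highpass", order = ord,
                     cutoff_note = "see filter history")
}

#' Duration-adaptive high-pass filtering of a recording
#'
#' Convenience wrapper: chooses the cutoff from the recording duration,
#' designs the kernel, and applies it with zero phase. Run after ASR: the
#' pipeline corrects bursts on unfiltered data so sharp-transition filtering
#' cannot smear brief artifacts across time first.
#'
#' @param rec An `eeg_recording`.
#' @param spec A [filter_spec()].
#' @param cutoff_hz Optional explicit cutoff overriding the duration rule.
#' @return The filtered recording, cutoff recorded in its history.
#' @export
highpass_recording <- function(rec, spec = filter_spec(), cutoff_hz = NULL) {
  fc <- cutoff_hz %||% choose_cutoff(duration_s(rec), spec)
  coeffs <- design_highpass(rec$fs, fc, spec)
  out <- apply_zero_phase(rec, coeffs)
  out$history[[length(out$history)]]$cutoff_hz <- fc
  out
}
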