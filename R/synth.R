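#' Synthetic-session specification
#'
#' Describes a simulated 16-channel, 125 Hz session: oscillatory and 1/f
#' brain-like sources mixed through a well-conditioned random matrix at a
#' physiological background amplitude (about 20 uV RMS), plus planted
#' artifacts with ground-truth masks. Generation is fully deterministic given
#' `seed`; the clean sources depend only on `seed`, so GT/MVMT profile pairs
#' built from the same seed share identical clean data for paired testing.
#'
#' Artifact entries are lists with a `kind` and kind-specific parameters:
#' * `impedance_channel` - `channel`, `offset_uv` (default 96000, twice the
#'   screening threshold): constant offset emulating poor electrode contact.
#' * `flatline_channel` - `channel`, `start_s` (0), `end_s` (start + 6):
#'   digitally constant segment.
#' * `uncorrelated_channel` - `channel`: replaced by independent noise at the
#'   background amplitude.
#' * `noisy_channel` - `channel`, `factor` (8): amplitude-scaled copy
#'   (a robust-z outlier that stays correlated with its neighbours).
#' * `burst` - `coverage` (0.1), `burst_s` (1), `factor` (20), `channels`
#'   (default all): transient motion-like noise bursts with a shared random
#'   topography per burst.
#' * `line_noise` - `freq` (50), `amplitude_uv` (5): mains sinusoid on all
#'   channels.
#' * `blink` - `rate_per_min` (12), `amplitude_uv` (100), `channels`
#'   (default the two frontal-most): low-frequency positive pulses.
#'
#' @param n_channels,fs,duration_s Recording geometry (defaults 16, 125, 60).
#' @param seed Mandatory integer seed.
#' @param sources List of `list(kind=, amplitude=)` with kinds `alpha_osc`
#'   (amplitude-modulated 10 Hz), `beta_osc` (20 Hz), `pink_noise`. Default:
#'   two alpha, one beta, three pink.
#' @param artifacts List of artifact entries (see above).
#' @param background_rms Target clean-signal RMS per channel in uV
#'   (default 20).
#' @param sensor_noise_rms Independent white amplifier/electrode noise per
#'   channel in uV RMS (default 0). Off by default so the clean background's
#'   rank equals the source count, keeping planted artifacts the only
#'   broadband content; set it positive to emulate noisy dry-contact
#'   hardware.
#' @param participant_id,condition,start_time Session identity fields.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_channels = 16, fs = 125, duration_s = 60, seed,
                       sources = NULL, artifacts = list(),
                       background_rms = 20, sensor_noise_rms = 0,
                       participant_id = "P01",
                       condition = "GT", start_time = 1.7e12) {
  if (missing(seed)) abort("`seed` is mandatory: synthetic sessions are fully deterministic.")
  sources <- sources %||% list(
    list(kind = "alpha_osc", amplitude = 1.0),
    list(kind = "alpha_osc", amplitude = 0.8),
    list(kind = "beta_osc", amplitude = 0.7),
    list(kind = "pink_noise", amplitude = 1.0),
    list(kind = "pink_noise", amplitude = 1.0),
    list(kind = "pink_noise", amplitude = 0.8))
  for (a in artifacts) {
    if (is.null(a$kind)) abort("Every artifact entry needs a `kind`.")
    iv <- c(a$start_s %||% 0, a$end_s %||% duration_s)
    if (iv[1] < 0 || iv[2] > duration_s || iv[1] >= iv[2])
      abort(sprintf("Artifact '%s' interval [%g, %g) outside [0, %g).",
                    a$kind, iv[1], iv[2], duration_s))
  }
  structure(list(n_channels = n_channels, fs = fs, duration_s = duration_s,
                 seed = as.integer(seed), sources = sources,
                 artifacts = artifacts, background_rms = background_rms,
                 sensor_noise_rms = sensor_noise_rms,
                 participant_id = participant_id,
                 condition = match.arg(condition, c("GT", "MVMT")),
                 start_time = start_time),
            class = "synth_spec")
}

pink_noise <- function(n, fs) {
  # 1/f spectral shaping with a white floor, flattened below 1 Hz (the band
  # the high-pass stage owns). The floor spreads each window's energy over
  # many degrees of freedom so the background RMS is stationary at the
  # burst-detection timescale.
  z <- fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) * fs / n
  x <- Re(fft(z * sqrt(1 / pmax(f, 1) + 0.15), inverse = TRUE)) / n
  as.numeric(scale(x))
}

make_source <- function(kind, n, fs) {
  t <- (0:(n - 1)) / fs
  switch(kind,
    alpha_osc = {
      env <- 0.85 + 0.15 * sin(2 * pi * stats::runif(1, 0.05, 0.2) * t +
                                 stats::runif(1, 0, 2 * pi))
      x <- sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi)) * env
      as.numeric(scale(x))
    },
    beta_osc = {
      env <- 0.85 + 0.15 * sin(2 * pi * stats::runif(1, 0.1, 0.3) * t +
                                 stats::runif(1, 0, 2 * pi))
      as.numeric(scale(sin(2 * pi * 20 * t + stats::runif(1, 0, 2 * pi)) * env))
    },
    pink_noise = pink_noise(n, fs),
    abort(sprintf("Unknown source kind '%s'.", kind)))
}

# Random mixing matrix emulating volume conduction: every channel loads on a
# shared weighting of the sources (so channels are strongly mutually
# correlated, as scalp EEG is) plus a per-channel perturbation. Singular
# values are floored at 1/cond of the largest so ICA recovery is well-posed.
random_mixing <- function(k, s, cond = 10, spread = 0.25) {
  w <- stats::runif(s, 0.7, 1.3)
  w <- w / sqrt(sum(w^2))
  A <- rep(1, k) %*% t(w) +
    spread * matrix(stats::rnorm(k * s), k, s) / sqrt(s)
  sv <- svd(A)
  d <- pmax(sv$d, sv$d[1] / cond)
  sv$u %*% (d * t(sv$v))
}

#' Generate a synthetic session with ground truth
#'
#' @param spec A [synth_spec()].
#' @return A list of class `synth_session`: `recording` (with artifacts),
#'   `meta` (a [session_meta()] with the gameplay interval and two mini-game
#'   entries), and `ground_truth` (clean data, mixing, sources, per-kind
#'   artifact masks, and the exact artifact contribution
#'   `recording$data - clean`).
#' @export
generate_session <- function(spec) {
  n <- round(spec$duration_s * spec$fs)
  k <- spec$n_channels
  fs <- spec$fs
  # clean sources and mixing depend on the seed alone (profile pairing)
  clean_parts <- with_local_seed(spec$seed, {
    S <- do.call(rbind, lapply(spec$sources, function(s)
      s$amplitude * make_source(s$kind, n, fs)))
    A <- random_mixing(k, nrow(S))
    noise <- if (spec$sensor_noise_rms > 0)
      matrix(stats::rnorm(k * n, sd = spec$sensor_noise_rms), k, n)
    else matrix(0, k, n)
    list(S = S, A = A, noise = noise)
  })
  S <- clean_parts$S
  A <- clean_parts$A
  clean <- A %*% S
  clean <- clean * (spec$background_rms / sqrt(mean(clean^2))) +
    clean_parts$noise
  data <- clean
  masks <- list()
  t <- (0:(n - 1)) / fs

  data <- with_local_seed(spec$seed + 7919L, {
    for (a in spec$artifacts) {
      ch <- a$channel %||% NULL
      switch(a$kind,
        impedance_channel = {
          ch <- ch %||% 1L
          data[ch, ] <- data[ch, ] + (a$offset_uv %||% 96000)
          masks$impedance_channel <- c(masks$impedance_channel, ch)
        },
        flatline_channel = {
          ch <- ch %||% 1L
          i0 <- round((a$start_s %||% 0) * fs) + 1L
          i1 <- min(n, round((a$end_s %||% ((a$start_s %||% 0) + 6)) * fs))
          data[ch, i0:i1] <- data[ch, i0]
          masks$flatline_channel <- c(masks$flatline_channel, ch)
        },
        uncorrelated_channel = {
          ch <- ch %||% 1L
          data[ch, ] <- stats::rnorm(n, sd = spec$background_rms)
          masks$uncorrelated_channel <- c(masks$uncorrelated_channel, ch)
        },
        noisy_channel = {
          ch <- ch %||% 1L
          data[ch, ] <- data[ch, ] * (a$factor %||% 8)
          masks$noisy_channel <- c(masks$noisy_channel, ch)
        },
        burst = {
          chans <- a$channels %||% seq_len(k)
          coverage <- a$coverage %||% 0.1
          bs <- a$burst_s %||% 1
          factor <- a$factor %||% 20
          nb <- max(1L, round(coverage * spec$duration_s / bs))
          L <- round(bs * fs)
          slots <- floor(n / L)
          starts <- (sort(sample.int(slots, min(nb, slots))) - 1L) * L
          mask <- masks$burst %||% rep(FALSE, n)
          taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = L))
          nc <- length(chans)
          for (s0 in starts) {
            idx <- (s0 + 1L):(s0 + L)
            # motion bursts are spatially coherent: a dominant common-mode
            # pattern (all electrodes move together) plus up to two weaker
            # spatial modes, not independent noise per channel
            r_src <- min(3L, nc)
            topo <- cbind(stats::runif(nc, 0.7, 1.3),
                          matrix(stats::rnorm(nc * (r_src - 1L), sd = 0.3),
                                 nc, r_src - 1L))
            Z <- matrix(stats::rnorm(r_src * L), r_src, L)
            amp <- factor * spec$background_rms / sqrt(rowSums(topo^2))
            data[chans, idx] <- data[chans, idx] +
              (topo * amp) %*% Z * rep(taper, each = nc)
            mask[idx] <- TRUE
          }
          masks$burst <- mask
        },
        line_noise = {
          amp <- a$amplitude_uv %||% 5
          freq <- a$freq %||% 50
          phase <- stats::runif(k, 0, 2 * pi)
          gains <- stats::runif(k, 0.5, 1.5)
          data <- data + amp * gains *
            sin(outer(rep(1, k), 2 * pi * freq * t) + phase)
          masks$line_noise <- seq_len(k)
        },
        blink = {
          chans <- a$channels %||% c(1L, 2L)
          rate <- a$rate_per_min %||% 12
          amp <- a$amplitude_uv %||% 60
          n_blinks <- max(1L, round(rate * spec$duration_s / 60))
          centers <- sort(stats::runif(n_blinks, 0.5, spec$duration_s - 0.5))
          mask <- masks$blink %||% rep(FALSE, n)
          wts <- seq(1, 0.6, length.out = length(chans))
          for (cts in centers) {
            pulse <- amp * exp(-((t - cts)^2) / (2 * 0.15^2))
            on <- pulse > 0.01 * amp
            data[chans, ] <- data[chans, ] + outer(wts, pulse)
            mask[on] <- TRUE
          }
          masks$blink <- mask
        },
        abort(sprintf("Unknown artifact kind '%s'.", a$kind)))
    }
    data
  })

  rec <- eeg_recording(data, fs, start_time = spec$start_time)
  rec <- annotate_recording(rec, "synth", seed = spec$seed,
                            condition = spec$condition)
  mid <- spec$start_time + spec$duration_s * 1000 / 2
  margin_ms <- min(2000, spec$duration_s * 250)  # gameplay inside recording
  meta <- session_meta(
    participant_id = spec$participant_id, condition = spec$condition,
    gameplay_start = spec$start_time + margin_ms,
    gameplay_end = spec$start_time + spec$duration_s * 1000 - margin_ms,
    buffer_s = 2,
    minigames = list(
      list(label = "memory", index = 1L,
           start = spec$start_time + margin_ms, end = mid, adjustment_s = 0),
      list(label = "attention", index = 1L, start = mid,
           end = spec$start_time + spec$duration_s * 1000 - margin_ms,
           adjustment_s = 0)))
  gt <- list(clean = clean, mixing = A, sources = S, masks = masks,
             artifact_delta = data - clean)
  structure(list(recording = rec, meta = meta, ground_truth = gt,
                 spec = spec),
            class = "synth_session")
}

#' Condition presets
#'
#' `gt_profile()` emulates the still baseline: no motion bursts, mild line
#' noise only. `mvmt_profile()` emulates full-body movement: dense motion
#' bursts (10% coverage), blinks, and one uncorrelated channel. Both keep the
#' base spec's seed, so their clean sources are identical (paired testing).
#'
#' @param spec A base [synth_spec()].
#' @return A modified `synth_spec`.
#' @export
gt_profile <- function(spec) {
  spec$condition <- "GT"
  spec$artifacts <- list(list(kind = "line_noise", amplitude_uv = 2))
  spec
}

#' @rdname gt_profile
#' @export
mvmt_profile <- function(spec) {
  spec$condition <- "MVMT"
  spec$artifacts <- list(
    list(kind = "burst", coverage = 0.1, burst_s = 1, factor = 20),
    list(kind = "blink", rate_per_min = 12),
    list(kind = "uncorrelated_channel", channel = spec$n_channels - 2L),
    list(kind = "line_noise", amplitude_uv = 2))
  spec
}

#' Write a recording in the OpenBCI GUI text dialect
#'
#' '%'-prefixed header lines, a column-name line, then comma-separated rows:
#' cycling sample index, the EXG channels, three zeroed accelerometer
#' columns, and the absolute timestamp in ms.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_openbci_txt <- function(rec, path) {
  k <- n_channels(rec)
  n <- n_samples(rec)
  header <- c("%OpenBCI Raw EXG Data",
              sprintf("%%Number of channels = %d", k),
              sprintf("%%Sample Rate = %g Hz", rec$fs),
              "%Board = OpenBCI_GUI$BoardCytonSerialDaisy")
  cols <- c("Sample Index", rec$channel_labels,
            sprintf("Accel Channel %d", 0:2), "Timestamp")
  ts <- rec$start_time + (seq_len(n) - 1L) / rec$fs * 1000
  rows <- cbind((seq_len(n) - 1L) %% 256L,
                t(rec$data),
                matrix(0, n, 3), ts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(cols, collapse = ","), con)
  utils::write.table(format(rows, trim = TRUE, digits = 10, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
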