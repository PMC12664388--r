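# Shared fixtures, all generated in code at test time.

fs_default <- 125

# Plain multichannel noise recording (channels mutually independent).
noise_recording <- function(k = 4, dur = 10, fs = fs_default, sd = 20,
                            seed = 1) {
  withr::with_seed(seed,
    eeg_recording(matrix(rnorm(k * dur * fs, sd = sd), nrow = k), fs = fs))
}

# Recording whose channels all share one source, plus optional extras.
shared_source_recording <- function(k = 9, dur = 10, fs = fs_default,
                                    seed = 2) {
  withr::with_seed(seed, {
    src <- rnorm(dur * fs)
    eeg_recording(matrix(rep(src, k), nrow = k, byrow = TRUE) +
                    matrix(rnorm(k * dur * fs, sd = 0.05), nrow = k), fs = fs)
  })
}

# The 4-channel / 4-source blind-separation fixture: two super-Gaussian
# sources, one sub-Gaussian sinusoid, one uniform-noise source.
four_source_fixture <- function(n = 7500, fs = fs_default, seed = 123) {
  withr::with_seed(seed, {
    t <- (0:(n - 1)) / fs
    S <- rbind(
      sign(rnorm(n)) * abs(rnorm(n))^2,
      ifelse(runif(n) < 0.05, rnorm(n, sd = 6), rnorm(n, sd = 0.5)),
      sin(2 * pi * 10 * t),
      runif(n, -1, 1))
    S <- t(scale(t(S)))
    A <- matrix(c(1, .5, .3, .2, .4, 1, .5, .3,
                  .3, .4, 1, .5, .2, .3, .4, 1), 4, 4)
    list(rec = eeg_recording(A %*% S, fs), S = S, A = A)
  })
}

# Synthetic session with the five planted bad channels used throughout
# channel-screening checks.
bad_channel_session <- function(seed = 11) {
  generate_session(synth_spec(seed = seed, artifacts = list(
    list(kind = "impedance_channel", channel = 3L),
    list(kind = "impedance_channel", channel = 7L),
    list(kind = "flatline_channel", channel = 5L),
    list(kind = "uncorrelated_channel", channel = 10L),
    list(kind = "noisy_channel", channel = 14L))))
}

burst_session <- function(seed = 5, coverage = 0.1, channels = NULL) {
  art <- list(kind = "burst", coverage = coverage)
  if (!is.null(channels)) art$channels <- channels
  generate_session(synth_spec(seed = seed, artifacts = list(art)))
}

# Probability tables with given Brain probabilities (one IC per row of `bp`,
# one table per column). Residual mass goes on "Other" alone or is spread
# evenly over the six non-Brain categories.
brain_prob_tables <- function(bp, residual = c("other", "spread")) {
  residual <- match.arg(residual)
  bp <- as.matrix(bp)
  lapply(seq_len(ncol(bp)), function(v) {
    rest <- 1 - bp[, v]
    part <- if (residual == "other") 0 else rest / 6
    tb <- tibble::tibble(version = paste0("v", v), ic = seq_len(nrow(bp)),
                         brain = bp[, v], muscle = part, eye = part,
                         heart = part, line_noise = part,
                         channel_noise = part,
                         other = if (residual == "other") rest else part)
    class(tb) <- c("ic_prob_table", class(tb))
    tb
  })
}

# Frequency response of an FIR kernel, computed directly from its definition
# (independent of the design code).
fir_gain <- function(coeffs, f, fs) {
  k <- seq_along(coeffs) - 1
  vapply(f, function(fi) abs(sum(coeffs * exp(-2i * pi * fi * k / fs))),
         numeric(1))
}

# Amplitude of the sinusoid at frequency f contained in x (least squares).
tone_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  co <- stats::coef(stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t)))
  sqrt(co[2]^2 + co[3]^2)
}
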