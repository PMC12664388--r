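#' Channel-wise normalizations
#'
#' `zscore_normalize()` rescales each channel to mean 0, standard deviation 1
#' (for comparing relative power, entropy and similarity across methods);
#' `l2_normalize()` rescales each channel to unit Euclidean norm across time
#' (for comparing energy structure). Both are positive per-channel rescalings
#' and therefore leave rank, relative band power, spectral entropy and
#' correlations unchanged.
#'
#' @param rec An `eeg_recording`.
#' @return The normalized recording.
#' @export
zscore_normalize <- function(rec) {
  sds <- apply(rec$data, 1, sd)
  if (any(sds == 0))
    abort(sprintf("Constant channel(s) cannot be z-scored: %s",
                  paste(rec$channel_labels[sds == 0], collapse = ", ")))
  rec$data <- (rec$data - rowMeans(rec$data)) / sds
  annotate_recording(rec, "zscore_normalize")
}

#' @rdname zscore_normalize
#' @export
l2_normalize <- function(rec) {
  nrm <- sqrt(rowSums(rec$data^2))
  if (any(nrm == 0))
    abort(sprintf("Zero channel(s) cannot be L2-normalized: %s",
                  paste(rec$channel_labels[nrm == 0], collapse = ", ")))
  rec$data <- rec$data / nrm
  annotate_recording(rec, "l2_normalize")
}

as_signal_matrix <- function(x) {
  if (inherits(x, "eeg_recording")) x$data
  else if (is.numeric(x) && is.null(dim(x))) matrix(x, nrow = 1)
  else if (is.matrix(x)) x
  else abort("Expected an eeg_recording, numeric vector, or matrix.")
}

#' Spectral entropy of the power spectrum
#'
#' Shannon entropy (base 2) of the Welch PSD normalized to a probability mass
#' over frequency bins: maximal (`log2(n_bins)`) for a flat white spectrum,
#' small for a spectrum concentrated in one line. For a multichannel
#' recording the per-channel entropies are averaged.
#'
#' @param x An `eeg_recording` or numeric vector.
#' @param fs Sampling rate (taken from the recording if given one).
#' @param window_s,overlap Welch settings (2-s Hamming windows, 50% overlap).
#' @return Entropy in bits.
#' @export
spectral_entropy <- function(x, fs = NULL, window_s = 2, overlap = 0.5) {
  fs <- fs %||% x$fs
  X <- as_signal_matrix(x)
  mean(apply(X, 1, function(ch) {
    p <- welch_psd(ch, fs, window_s, overlap)
    m <- p$psd[p$freq > 0]
    tot <- sum(m)
    if (tot <= 0) abort("Zero total power; spectral entropy undefined.")
    q <- m / tot
    q <- q[q > 0]
    -sum(q * log2(q))
  }))
}

#' Relative power in a frequency band
#'
#' Welch-integrated power in `[f_lo, f_hi)` divided by total power (DC bin
#' excluded). Canonical defaults downstream: alpha 8-13 Hz, beta 13-30 Hz.
#'
#' @inheritParams spectral_entropy
#' @param band Numeric `c(f_lo, f_hi)` in Hz, inside `(0, fs/2]`.
#' @return Relative power in `[0, 1]`, averaged over channels.
#' @export
band_power <- function(x, fs = NULL, band, window_s = 2, overlap = 0.5) {
  fs <- fs %||% x$fs
  if (length(band) != 2 || band[1] >= band[2] || band[1] < 0 ||
      band[1] >= fs / 2)
    abort("`band` must be c(f_lo, f_hi) with 0 <= f_lo < f_hi and f_lo < fs/2.")
  X <- as_signal_matrix(x)
  mean(apply(X, 1, function(ch) {
    p <- welch_psd(ch, fs, window_s, overlap)
    keep <- p$freq > 0
    tot <- sum(p$psd[keep])
    if (tot <= 0) abort("Zero total power; band power undefined.")
    sum(p$psd[keep & p$freq >= band[1] & p$freq < band[2]]) / tot
  }))
}

#' Alpha-band SNR proxy
#'
#' The ratio of alpha-band (8-13 Hz) power to total power: a signal-quality
#' surrogate in the absence of task labels, bounded in `[0, 1]` and identical
#' by definition to `band_power(x, fs, c(8, 13))`.
#'
#' @inheritParams spectral_entropy
#' @param alpha_band Alpha band edges in Hz.
#' @return SNR proxy in `[0, 1]`.
#' @export
snr_proxy <- function(x, fs = NULL, alpha_band = c(8, 13),
                      window_s = 2, overlap = 0.5) {
  band_power(x, fs, alpha_band, window_s, overlap)
}

#' Mean per-channel Pearson correlation with the raw signal
#'
#' @param clean,raw `eeg_recording`s (or matrices) with identical channels
#'   and length; the raw signal must already be trimmed/aligned to the clean
#'   one.
#' @return Mean Pearson r over channels.
#' @export
correlation_to_raw <- function(clean, raw) {
  A <- as_signal_matrix(clean)
  B <- as_signal_matrix(raw)
  if (!all(dim(A) == dim(B)))
    abort(sprintf("Alignment error: clean is %dx%d but raw is %dx%d.",
                  nrow(A), ncol(A), nrow(B), ncol(B)))
  mean(vapply(seq_len(nrow(A)), function(i) cor(A[i, ], B[i, ]), numeric(1)))
}

#' Effective rank of a recording
#'
#' Number of singular values above `tol` times the largest: the effective
#' dimensionality of the cleaned signal, which channel removal and subspace
#' reconstruction can only decrease.
#'
#' @param x An `eeg_recording` or matrix.
#' @param tol Relative singular-value tolerance (default 1e-7).
#' @return Integer rank.
#' @export
effective_rank <- function(x, tol = 1e-7) {
  d <- svd(as_signal_matrix(x), nu = 0, nv = 0)$d
  sum(d > tol * d[1])
}

#' Summaries of retained-component classifications
#'
#' `brain_fraction` is the mean Brain probability across retained ICs
#' (per-IC probabilities averaged over versions first); `artifact_fraction`
#' is its complement; `n_brain_ics` counts retained ICs with Brain
#' probability >= 0.7; `n_artifact_ics` counts retained ICs whose argmax
#' category is non-Brain. With zero retained ICs the fractions are returned
#' as `NA` with `defined = FALSE` rather than propagating NaN.
#'
#' @param tables List of `ic_prob_table`s (the versions voted over).
#' @param decisions `vote_decisions` from [vote_retain()].
#' @param brain_p_high Threshold defining a confidently-brain IC (0.7).
#' @return A one-row tibble.
#' @export
ic_summary <- function(tables, decisions, brain_p_high = 0.7) {
  if (inherits(tables, "ic_prob_table")) tables <- list(tables)
  keep <- decisions$ic[decisions$retained]
  if (length(keep) == 0L)
    return(tibble(brain_fraction = NA_real_, artifact_fraction = NA_real_,
                  n_brain_ics = 0L, n_artifact_ics = 0L, n_retained = 0L,
                  defined = FALSE))
  mats <- lapply(tables, function(tb) as.matrix(as.data.frame(tb)[ICLABEL_CATEGORIES]))
  mean_probs <- Reduce(`+`, mats) / length(mats)   # n_ic x 7, version-averaged
  bp <- mean_probs[keep, "brain"]
  arg <- ICLABEL_CATEGORIES[max.col(mean_probs[keep, , drop = FALSE],
                                    ties.method = "first")]
  tibble(brain_fraction = mean(bp), artifact_fraction = 1 - mean(bp),
         n_brain_ics = sum(bp >= brain_p_high),
         n_artifact_ics = sum(arg != "brain"),
         n_retained = length(keep), defined = TRUE)
}

#' Paired comparison of a metric between two methods
#'
#' Paired two-sided t-test on the differences plus Cohen's d for paired data
#' (mean difference over the standard deviation of the differences). A
#' zero-variance difference vector is flagged as degenerate: `t = d = 0`,
#' `p = 1` when the methods agree exactly, signed infinite `t` otherwise.
#'
#' @param a,b Equal-length paired metric vectors (length >= 3).
#' @return A one-row tibble: `statistic`, `p_value`, `cohens_d`, `n`,
#'   `degenerate`.
#' @export
paired_compare <- function(a, b) {
  if (length(a) != length(b)) abort("Paired samples must have equal length.")
  if (length(a) < 3) abort("Need at least 3 pairs.")
  d <- a - b
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(tibble(statistic = 0, p_value = 1, cohens_d = 0, n = n,
                    degenerate = TRUE))
    return(tibble(statistic = sign(mean(d)) * Inf, p_value = 0,
                  cohens_d = sign(mean(d)) * Inf, n = n, degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
         cohens_d = mean(d) / sd(d), n = n, degenerate = FALSE)
}

#' Tidy per-session metric row
#'
#' Computes the full validation-metric set for one cleaned session against
#' its raw counterpart, under a chosen channel-wise normalization, as one
#' tidy row (rank is computed before normalization; it is scale-invariant
#' anyway).
#'
#' @param clean Cleaned `eeg_recording`.
#' @param raw Raw `eeg_recording` aligned to `clean`.
#' @param session_id,method Identifier strings for the row.
#' @param normalization `"zscore"`, `"l2"`, or `"none"`.
#' @param tables,decisions Optional classification tables and vote decisions
#'   for the IC-based summaries.
#' @return A one-row tibble.
#' @export
session_metrics <- function(clean, raw, session_id = "session",
                            method = "eegcleanse",
                            normalization = c("zscore", "l2", "none"),
                            tables = NULL, decisions = NULL) {
  normalization <- match.arg(normalization)
  rk <- effective_rank(clean)
  rv <- sum(apply(clean$data, 1, var))
  norm_fun <- switch(normalization, zscore = zscore_normalize,
                     l2 = l2_normalize, none = identity)
  cn <- norm_fun(clean)
  rn <- norm_fun(raw)
  row <- tibble(
    session_id = session_id, method = method, normalization = normalization,
    retained_variance = rv,
    spectral_entropy = spectral_entropy(cn),
    alpha_power = band_power(cn, band = c(8, 13)),
    beta_power = band_power(cn, band = c(13, 30)),
    snr_proxy = snr_proxy(cn),
    corr_to_raw = correlation_to_raw(cn, rn),
    rank = rk)
  if (!is.null(tables) && !is.null(decisions))
    row <- dplyr::bind_cols(row, ic_summary(tables, decisions))
  row
}
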