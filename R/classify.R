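#' Classify independent components into the seven categories
#'
#' Produces one probability row per IC over the categories Brain, Muscle,
#' Eye, Heart, Line Noise, Channel Noise, Other. The classifier is pluggable:
#' the default is the built-in spectral/topographic heuristic
#' ([heuristic_classifier()]); externally computed tables (e.g. from an
#' ICLabel run in EEGLAB) can be loaded with [read_ic_probabilities()] and
#' used directly by the voting stage instead.
#'
#' Rows that do not sum to one within 1e-6 are renormalized with a warning.
#'
#' @param dec A `mapped_decomposition` from [apply_decomposition()].
#' @param classifier A function `(activation, topography, fs) ->` named
#'   probability vector over the seven categories.
#' @return A tibble of class `ic_prob_table`: columns `version`, `ic`, and
#'   the seven category probabilities.
#' @export
classify_components <- function(dec, classifier = heuristic_classifier) {
  k <- nrow(dec$activations)
  rows <- purrr::map(seq_len(k), function(i) {
    p <- classifier(dec$activations[i, ], dec$model$mixing[, i],
                    dec$recording$fs)
    normalize_prob_row(p, sprintf("IC %d", i))
  })
  probs <- do.call(rbind, rows)
  out <- dplyr::bind_cols(
    tibble(version = dec$mapping, ic = seq_len(k)),
    as_tibble(probs))
  class(out) <- c("ic_prob_table", class(out))
  out
}

normalize_prob_row <- function(p, what) {
  if (is.null(names(p))) names(p) <- ICLABEL_CATEGORIES
  p <- p[ICLABEL_CATEGORIES]
  if (anyNA(p) || any(p < 0))
    abort(sprintf("%s: probabilities must be non-negative over %s.",
                  what, paste(ICLABEL_CATEGORIES, collapse = ", ")))
  s <- sum(p)
  if (abs(s - 1) > 1e-6) {
    warn(sprintf("%s: probabilities sum to %.4f; renormalizing.", what, s))
    p <- p / s
  }
  p
}

#' Read / write IC probability tables as CSV
#'
#' CSV interface for externally computed classifications: one row per IC with
#' an `ic` column and the seven category columns. Rows are validated and
#' renormalized under the same tolerance as [classify_components()].
#'
#' @param path CSV path.
#' @param version Mapping label to attach (e.g. `"clean_to_clean"`).
#' @return An `ic_prob_table` tibble.
#' @export
read_ic_probabilities <- function(path, version = "external") {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(c("ic", ICLABEL_CATEGORIES), names(df))
  if (length(missing))
    abort(sprintf("Probability CSV %s lacks columns: %s", path,
                  paste(missing, collapse = ", ")))
  probs <- t(apply(df[ICLABEL_CATEGORIES], 1, normalize_prob_row, what = path))
  out <- dplyr::bind_cols(tibble(version = version, ic = df$ic),
                          as_tibble(probs))
  class(out) <- c("ic_prob_table", class(out))
  out
}

#' @rdname read_ic_probabilities
#' @param table An `ic_prob_table`.
#' @export
write_ic_probabilities <- function(table, path) {
  utils::write.csv(as.data.frame(table)[c("ic", ICLABEL_CATEGORIES)], path,
                   row.names = FALSE)
  invisible(path)
}

#' @export
autoplot.ic_prob_table <- function(object, ...) {
  df <- tidyr::pivot_longer(object, dplyr::all_of(ICLABEL_CATEGORIES),
                            names_to = "category", values_to = "p")
  df$category <- factor(df$category, levels = rev(ICLABEL_CATEGORIES))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$ic), .data$category,
                                   fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "independent component", y = NULL, fill = "p") +
    ggplot2::theme_minimal()
}

#' Heuristic component classifier
#'
#' A transparent stand-in for a trained IC classifier, scoring hand-crafted
#' spectral and topographic features and passing them through a softmax:
#' alpha-band (8-13 Hz) and, more weakly, beta-band (13-30 Hz) excess over a
#' flat spectrum scores Brain, as does a negative 1/f spectral slope
#' (broadband background brain activity); >20 Hz
#' broadband dominance scores Muscle; low-frequency (<4 Hz) power with heavy
#' tails scores Eye; concentration at the mains frequency scores Line Noise;
#' a topography loading on a single channel scores Channel Noise; Heart and
#' Other carry small baselines so featureless components come out diffuse.
#' All band scores are excesses over the flat-spectrum expectation, so white
#' noise receives no confident label.
#'
#' @param activation Component time course.
#' @param topography Mixing-matrix column for the component.
#' @param fs Sampling rate in Hz.
#' @param line_freq Mains frequency (default 50 Hz).
#' @return Named probability vector over the seven categories.
#' @export
heuristic_classifier <- function(activation, topography, fs, line_freq = 50) {
  p <- welch_psd(activation, fs)
  keep <- p$freq > 0
  f <- p$freq[keep]
  ps <- p$psd[keep]
  tot <- sum(ps)
  if (tot <= 0) return(stats::setNames(rep(1 / 7, 7), ICLABEL_CATEGORIES))
  nyq <- fs / 2
  mass <- function(lo, hi) sum(ps[f >= lo & f < hi]) / tot
  bw <- function(lo, hi) (min(hi, nyq) - lo) / nyq  # flat-spectrum expectation
  p_alpha <- mass(8, 13); p_beta <- mass(13, 30)
  p_low <- mass(0, 4); p_high <- mass(20, nyq)
  p_line <- mass(line_freq - 1, line_freq + 1)
  # 1/f^a spectral slope over 2-40 Hz: brain background activity shows a
  # clearly negative log-log slope, unlike white broadband artifacts
  sl_band <- f >= 2 & f <= 40 & ps > 0
  slope <- if (sum(sl_band) > 4)
    stats::coef(stats::lm(log(ps[sl_band]) ~ log(f[sl_band])))[[2]] else 0
  m2 <- mean((activation - mean(activation))^2)
  kurt <- if (m2 > 0) mean((activation - mean(activation))^4) / m2^2 - 3 else 0
  conc <- if (sum(topography^2) > 0) max(topography^2) / sum(topography^2) else 0
  scores <- c(
    brain = 8 * max(0, p_alpha - bw(8, 13)) +
      3 * max(0, p_beta - bw(13, 30)) +
      1.5 * max(0, min(1, -slope)),
    muscle = 6 * max(0, (p_high - p_line) - (bw(20, nyq) - bw(line_freq - 1, line_freq + 1))),
    eye = 6 * max(0, p_low - bw(0, 4)) * (0.5 + 0.5 * tanh((kurt - 1) / 4)),
    heart = 0.1,
    line_noise = 10 * max(0, p_line - bw(line_freq - 1, line_freq + 1)),
    channel_noise = 8 * max(0, conc - 0.6),
    other = 0.8)
  e <- exp(scores - max(scores))
  stats::setNames(e / sum(e), ICLABEL_CATEGORIES)
}
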