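#' Voting configuration
#'
#' Thresholds of the four-criterion hybrid voting rule that retains an IC as
#' brain-related when *any* criterion fires:
#' * C1 - Brain probability at least `p_two` in at least two versions.
#' * C2 - one version at or above `p_high` and no version contradicts it
#'   (a contradiction is a non-Brain argmax with probability at least
#'   `contradiction_p`).
#' * C3 - weighted average Brain probability strictly above
#'   `conservative_avg`.
#' * C4 - a strict majority of versions has Brain as argmax with probability
#'   at least `p_moderate`.
#'
#' @param p_two C1 per-version threshold (default 0.6).
#' @param p_high C2 high-confidence threshold (default 0.7).
#' @param conservative_avg C3 conservative average threshold (default 0.5).
#' @param p_moderate C4 moderate-confidence threshold (default 0.5).
#' @param contradiction_p Confidence a non-Brain argmax needs to veto C2
#'   (default 0.6, symmetric with C1).
#' @param weights Optional per-version weights for the C3 average
#'   (default equal).
#' @return A list of class `vote_config`.
#' @export
vote_config <- function(p_two = 0.6, p_high = 0.7, conservative_avg = 0.5,
                        p_moderate = 0.5, contradiction_p = 0.6,
                        weights = NULL) {
  stopifnot(p_two <= p_high, p_moderate <= p_two)
  structure(list(p_two = p_two, p_high = p_high,
                 conservative_avg = conservative_avg,
                 p_moderate = p_moderate, contradiction_p = contradiction_p,
                 weights = weights),
            class = "vote_config")
}

#' Hybrid voting over component classifications
#'
#' Evaluates the four retention criteria per IC over one to three aligned
#' probability tables (one per ICA-to-signal mapping; alignment by IC index
#' is valid because mappings sharing a source model share its component
#' basis). All fired criteria are recorded, not just the first. With a single
#' table, C1 cannot fire and C4 reduces to that version's own verdict.
#'
#' @param tables A list of `ic_prob_table` tibbles (or a single table), all
#'   with the same ICs.
#' @param cfg A [vote_config()].
#' @return A tibble of class `vote_decisions`: `ic`, `retained`, logical
#'   columns `c1`-`c4`, and a `brain_p` list-column of per-version Brain
#'   probabilities.
#' @export
vote_retain <- function(tables, cfg = vote_config()) {
  if (inherits(tables, "ic_prob_table")) tables <- list(tables)
  if (length(tables) == 0L) abort("At least one probability table is required.")
  n_ic <- unique(vapply(tables, nrow, integer(1)))
  if (length(n_ic) != 1L)
    abort("Probability tables are not aligned: differing IC counts.")
  v <- length(tables)
  w <- cfg$weights %||% rep(1, v)
  if (length(w) != v) abort("`weights` must have one entry per version.")
  w <- w / sum(w)

  cat_mat <- function(tb) as.matrix(as.data.frame(tb)[ICLABEL_CATEGORIES])
  mats <- lapply(tables, cat_mat)
  decisions <- purrr::map(seq_len(n_ic), function(i) {
    probs <- do.call(rbind, lapply(mats, function(m) m[i, ]))  # v x 7
    bp <- probs[, "brain"]
    arg <- ICLABEL_CATEGORIES[max.col(probs, ties.method = "first")]
    maxp <- apply(probs, 1, max)
    c1 <- sum(bp >= cfg$p_two) >= 2
    contradicted <- any(arg != "brain" & maxp >= cfg$contradiction_p)
    c2 <- any(bp >= cfg$p_high) && !contradicted
    c3 <- sum(w * bp) > cfg$conservative_avg
    c4 <- sum(arg == "brain" & bp >= cfg$p_moderate) > v / 2
    tibble(ic = i, retained = c1 || c2 || c3 || c4,
           c1 = c1, c2 = c2, c3 = c3, c4 = c4, brain_p = list(unname(bp)))
  })
  out <- dplyr::bind_rows(decisions)
  class(out) <- c("vote_decisions", class(out))
  out
}

#' Reconstruct the brain-only signal from retained components
#'
#' Projects the retained ICs back into channel space:
#' `mixing[, retained] %*% activations[retained, ]`. Channel count and length
#' are preserved. With every IC retained this is the (rank-limited) identity;
#' with none, the session is marked excluded rather than erroring.
#'
#' @param dec The `mapped_decomposition` to reconstruct from (the filtered
#'   version by default in the pipeline; any mapping works).
#' @param decisions A `vote_decisions` tibble from [vote_retain()].
#' @return A list: `recording` (brain-only, `NULL` when excluded),
#'   `retained` (IC indices), `status`.
#' @export
reconstruct_brain_signal <- function(dec, decisions) {
  keep <- decisions$ic[decisions$retained]
  if (length(keep) == 0L)
    return(list(recording = NULL, retained = integer(), status = "excluded"))
  Y <- dec$model$mixing[, keep, drop = FALSE] %*%
    dec$activations[keep, , drop = FALSE]
  out <- dec$recording
  out$data <- Y
  rownames(out$data) <- out$channel_labels
  out <- annotate_recording(out, "brain_reconstruction",
                            n_retained = length(keep), retained = keep)
  list(recording = out, retained = keep, status = "ok")
}

#' @export
tidy.vote_decisions <- function(x, ...) {
  x |>
    dplyr::mutate(version = purrr::map(.data$brain_p, seq_along)) |>
    tidyr::unnest(c("version", "brain_p")) |>
    dplyr::select("ic", "version", "brain_p", "retained",
                  "c1", "c2", "c3", "c4")
}

#' @export
glance.vote_decisions <- function(x, ...) {
  tibble(n_ics = nrow(x), n_retained = sum(x$retained),
         retention_pct = 100 * mean(x$retained),
         n_c1 = sum(x$c1), n_c2 = sum(x$c2),
         n_c3 = sum(x$c3), n_c4 = sum(x$c4))
}

#' @export
autoplot.vote_decisions <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$ic), .data$brain_p,
                                   colour = .data$retained)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = c(0.6, 0.7), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = "independent component", y = "Brain probability") +
    ggplot2::theme_minimal()
}
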