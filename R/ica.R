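#' Extended-infomax ICA decomposition
#'
#' Fits extended infomax ICA (natural-gradient infomax with kurtosis-based
#' switching between super- and sub-Gaussian score functions, as in EEGLAB's
#' `runica` extended mode) to a recording. The data are centered per channel
#' and, if rank-deficient, projected onto their principal subspace first; the
#' sphering matrix is `inv(sqrtm(cov))`, so the sphered data have identity
#' covariance. The block order is randomly
#' permuted each pass, so the `seed` fully determines the result.
#'
#' Components are ordered by descending explained variance of their mixing
#' columns (times activation variance), with the sign fixed so each mixing
#' column's largest-magnitude entry is positive, making indices stable across
#' runs.
#'
#' @param rec An `eeg_recording` with at least `20 * k^2` samples for `k`
#'   channels (shorter recordings are excluded from decomposition).
#' @param seed Integer RNG seed recorded in the model (default 97).
#' @param max_iter Iteration cap (default 512).
#' @param w_change_tol Convergence tolerance on the weight change
#'   (default 1e-6).
#' @return A list of class `ica_model`: `weights` (r x r), `sphere` (r x k,
#'   including any rank-reduction projection), `unmixing = weights %*% sphere`
#'   (r x k), `mixing` (pseudo-inverse, k x r), `rank`, `seed`, `iterations`,
#'   `converged`, `source_version`, and channel metadata.
#' @export
fit_extended_infomax <- function(rec, seed = 97, max_iter = 512,
                                 w_change_tol = 1e-6) {
  X <- rec$data
  k <- nrow(X)
  n <- ncol(X)
  if (n < 20 * k^2)
    abort(sprintf(
      "Recording too short for ICA: %d samples < 20 * %d^2; session excluded.",
      n, k), class = "eegcleanse_excluded")
  Xc <- X - rowMeans(X)
  C <- Xc %*% t(Xc) / (n - 1)
  eg <- eigen(C, symmetric = TRUE)
  r <- sum(eg$values > 1e-9 * max(eg$values))
  P <- diag(k)
  if (r < k) {
    warn(sprintf("Data rank %d < %d channels; decomposing the rank-reduced subspace.",
                 r, k))
    P <- eg$vectors[, 1:r, drop = FALSE]
    Xr <- t(P) %*% Xc
    C <- Xr %*% t(Xr) / (n - 1)
    eg <- eigen(C, symmetric = TRUE)
  } else Xr <- Xc
  sph_r <- eg$vectors %*% ((1 / sqrt(eg$values[1:r])) * t(eg$vectors))
  Xw <- sph_r %*% Xr

  fit <- with_local_seed(seed, infomax_core(Xw, max_iter, w_change_tol))
  W <- fit$W
  sphere <- sph_r %*% t(P)           # r x k
  unmixing <- W %*% sphere
  act <- unmixing %*% X
  mixing <- MASS::ginv(unmixing)
  # stable ordering + sign convention
  pow <- colSums(mixing^2) * apply(act, 1, var)
  ord <- order(pow, decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  flip <- vapply(seq_len(r), function(i) {
    col <- mixing[, ord[i]]
    sign(col[which.max(abs(col))])
  }, numeric(1))
  flip[flip == 0] <- 1
  W <- W * flip
  unmixing <- W %*% sphere
  mixing <- MASS::ginv(unmixing)
  structure(list(weights = W, sphere = sphere, unmixing = unmixing,
                 mixing = mixing, rank = r, seed = seed,
                 iterations = fit$iterations, converged = fit$converged,
                 source_version = NA_character_,
                 channel_labels = rec$channel_labels, fs = rec$fs),
            class = "ica_model")
}

# Natural-gradient extended infomax on sphered data (r x n). Follows the
# runica conventions: block updates, learning-rate annealing driven by the
# angle between successive weight changes, kurtosis-based sign switching.
infomax_core <- function(Xw, max_iter, w_change_tol) {
  r <- nrow(Xw)
  n <- ncol(Xw)
  W <- diag(r)
  block <- max(8L, min(512L, floor(sqrt(n / 3))))
  lrate <- 0.00065 / log(r + 1) * 10
  anneal <- 0.98
  annealdeg <- 60
  signs <- rep(1, r)
  oldW <- W
  olddelta <- NULL
  change <- Inf
  iter <- 0L
  max_weight <- 1e8
  while (iter < max_iter) {
    iter <- iter + 1L
    # sub/super-Gaussian switching from activation kurtosis
    u_all <- W %*% Xw
    kurt <- rowMeans(u_all^4) / rowMeans(u_all^2)^2 - 3
    signs <- ifelse(kurt < 0, -1, 1)
    perm <- sample.int(n)
    blow <- FALSE
    for (s in seq(1L, n - block + 1L, by = block)) {
      u <- W %*% Xw[, perm[s:(s + block - 1L)], drop = FALSE]
      y <- tanh(u)
      W <- W + lrate * (block * diag(r) - (signs * y) %*% t(u) - u %*% t(u)) %*% W
      if (max(abs(W)) > max_weight) { blow <- TRUE; break }
    }
    if (blow) {  # restart with a gentler learning rate
      W <- diag(r); oldW <- W; olddelta <- NULL
      lrate <- lrate * 0.8
      next
    }
    delta <- as.vector(W - oldW)
    change <- sum(delta^2)
    if (!is.null(olddelta)) {
      denom <- sqrt(sum(delta^2) * sum(olddelta^2))
      angle <- if (denom > 0)
        acos(max(-1, min(1, sum(delta * olddelta) / denom))) * 180 / pi
      else 0
      if (angle > annealdeg) lrate <- lrate * anneal
    }
    olddelta <- delta
    oldW <- W
    if (change < w_change_tol) break
  }
  if (change >= w_change_tol && iter >= max_iter)
    warn(sprintf("Extended infomax did not reach tolerance %g in %d iterations (last change %.3g).",
                 w_change_tol, max_iter, change))
  list(W = W, iterations = iter, converged = change < w_change_tol)
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf("<ica_model> %d components on %d channels (rank %d), seed %d, %d iterations%s\n",
              nrow(x$unmixing), length(x$channel_labels), x$rank, x$seed,
              x$iterations, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Apply an ICA decomposition to a (possibly different) signal version
#'
#' Transfers a fitted model onto a target recording with the identical channel
#' set: the component activations are `unmixing %*% data` and the mixing
#' matrix is recomputed from scratch as the pseudo-inverse of the unmixing.
#' This supports the three version mappings used for robust component
#' labeling: clean-to-clean, filtered-to-filtered, and filtered-to-clean.
#'
#' @param model An `ica_model`.
#' @param rec Target `eeg_recording` with the same channels as the model.
#' @param mapping One of `"clean_to_clean"`, `"filtered_to_filtered"`,
#'   `"filtered_to_clean"`.
#' @return A list of class `mapped_decomposition`: `mapping`, `model`
#'   (with mixing recomputed), `activations` (components x samples), and the
#'   target `recording`.
#' @export
apply_decomposition <- function(model, rec,
                                mapping = c("clean_to_clean",
                                            "filtered_to_filtered",
                                            "filtered_to_clean")) {
  mapping <- match.arg(mapping)
  if (!identical(model$channel_labels, rec$channel_labels)) {
    diff <- union(setdiff(model$channel_labels, rec$channel_labels),
                  setdiff(rec$channel_labels, model$channel_labels))
    abort(sprintf("Channel sets differ between model and recording: %s",
                  paste(diff, collapse = ", ")))
  }
  model$mixing <- MASS::ginv(model$unmixing)
  structure(list(mapping = mapping, model = model,
                 activations = model$unmixing %*% rec$data,
                 recording = rec),
            class = "mapped_decomposition")
}

#' Fit both dataset versions and build the three labeling mappings
#'
#' Fits extended infomax separately on the ASR-cleaned and the high-pass
#' filtered versions of a session (seed and seed + 1), then emits the three
#' ICA-to-signal mappings consumed by the voting stage. If the filtered fit
#' fails, only clean-to-clean is emitted; if both fail, the session is marked
#' excluded.
#'
#' @param clean_rec ASR-cleaned `eeg_recording`.
#' @param filt_rec High-pass-filtered `eeg_recording` (same channels/length).
#' @param seed Integer seed.
#' @return A list: `mappings` (list of `mapped_decomposition`), `models`,
#'   `status` (`"ok"` or `"excluded"`), `log` (character).
#' @export
build_versions <- function(clean_rec, filt_rec, seed = 97) {
  log <- character()
  fit_try <- function(rec, sd, version) {
    tryCatch({
      m <- fit_extended_infomax(rec, seed = sd)
      m$source_version <- version
      m
    }, error = function(e) {
      log <<- c(log, sprintf("%s fit failed: %s", version, conditionMessage(e)))
      NULL
    })
  }
  clean_model <- fit_try(clean_rec, seed, "clean")
  filt_model <- fit_try(filt_rec, seed + 1L, "filtered")
  mappings <- list()
  if (!is.null(clean_model))
    mappings$clean_to_clean <-
      apply_decomposition(clean_model, clean_rec, "clean_to_clean")
  if (!is.null(filt_model)) {
    mappings$filtered_to_filtered <-
      apply_decomposition(filt_model, filt_rec, "filtered_to_filtered")
    mappings$filtered_to_clean <-
      apply_decomposition(filt_model, clean_rec, "filtered_to_clean")
  }
  status <- if (length(mappings) == 0L) "excluded" else "ok"
  if (length(mappings) < 3L)
    log <- c(log, sprintf("%d of 3 mappings emitted", length(mappings)))
  list(mappings = mappings,
       models = list(clean = clean_model, filtered = filt_model),
       status = status, log = log)
}
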