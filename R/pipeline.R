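#' Run the full cleaning pipeline on one session
#'
#' Executes every stage in the pipeline's fixed order: channel screening
#' (high-impedance first, then flatline/low-correlation/noisy on the
#' survivors), ASR on the channel-cleaned *unfiltered* data (clean-reference
#' selection, calibration, reconstruction, window rejection), duration-
#' adaptive zero-phase high-pass filtering, dual extended-infomax ICA with
#' the three version mappings, component classification, hybrid voting, and
#' brain-only reconstruction (from the filtered version by default, since it
#' feeds downstream analysis).
#'
#' Any stage may mark the session excluded (too few clean channels, no data
#' left after window rejection, both ICA fits failing, or zero retained
#' brain ICs); the result then carries the partial report and an `"excluded"`
#' status instead of erroring.
#'
#' @param rec A raw or ingested `eeg_recording` (already trimmed/segmented).
#' @param screen_cfg,asr_cfg,fir_spec,vote_cfg Stage configurations.
#' @param classifier Component classifier function (see
#'   [classify_components()]); replaceable by externally computed tables via
#'   `prob_tables`.
#' @param prob_tables Optional list of pre-computed `ic_prob_table`s keyed by
#'   mapping name, bypassing `classifier`.
#' @param reconstruct_from `"filtered_to_filtered"` (default) or any other
#'   mapping to reconstruct the brain-only signal from.
#' @param seed Integer seed controlling ICA; everything else is
#'   deterministic.
#' @return A list of class `eegcleanse_result`: `recording` (brain-only,
#'   `NULL` if excluded), `status`, `excluded_at`, and `report` (a
#'   `cleaning_report`).
#' @export
run_pipeline <- function(rec, screen_cfg = screen_config(),
                         asr_cfg = asr_config(), fir_spec = filter_spec(),
                         vote_cfg = vote_config(),
                         classifier = heuristic_classifier,
                         prob_tables = NULL,
                         reconstruct_from = "filtered_to_filtered",
                         seed = 97) {
  report <- list()
  excluded <- function(stage) {
    structure(list(recording = NULL, status = "excluded",
                   excluded_at = stage, report = new_cleaning_report(report)),
              class = "eegcleanse_result")
  }

  scr <- screen_channels(rec, screen_cfg)
  report$channels <- scr
  if (scr$status == "excluded") return(excluded("channel_screen"))

  ref <- find_clean_reference(scr$recording, asr_cfg)
  state <- calibrate_asr(scr$recording, ref, asr_cfg)
  asr <- apply_asr(scr$recording, state, asr_cfg)
  rej <- reject_bad_windows(asr$recording, state, asr_cfg)
  report$asr <- list(clean_fraction = ref$clean_fraction,
                     reconstructed_fraction = asr$reconstructed_fraction,
                     dropped = rej$dropped,
                     channel_flags = ref$channel_flags)
  if (rej$status == "excluded") return(excluded("asr_window_rejection"))
  clean_rec <- rej$recording

  filt_rec <- highpass_recording(clean_rec, fir_spec)
  report$filter <- list(
    cutoff_hz = filt_rec$history[[length(filt_rec$history)]]$cutoff_hz,
    duration_s = duration_s(filt_rec))

  versions <- build_versions(clean_rec, filt_rec, seed = seed)
  report$ica <- list(status = versions$status,
                     n_mappings = length(versions$mappings),
                     log = versions$log)
  if (versions$status == "excluded") return(excluded("ica"))

  tables <- prob_tables %||%
    lapply(versions$mappings, classify_components, classifier = classifier)
  decisions <- vote_retain(unname(tables), vote_cfg)
  report$votes <- decisions
  report$probabilities <- tables
  report$ic_summary <- ic_summary(unname(tables), decisions)

  target <- versions$mappings[[reconstruct_from]] %||% versions$mappings[[1]]
  recon <- reconstruct_brain_signal(target, decisions)
  report$reconstruction <- list(target = target$mapping,
                                retained = recon$retained,
                                status = recon$status)
  if (recon$status == "excluded") return(excluded("ic_vote"))

  structure(list(recording = recon$recording, status = "ok",
                 excluded_at = NA_character_,
                 report = new_cleaning_report(report)),
            class = "eegcleanse_result")
}

new_cleaning_report <- function(parts) structure(parts, class = "cleaning_report")

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  if (!is.null(x$channels))
    cat(sprintf("  channels: %d/%d retained\n",
                x$channels$n_retained, x$channels$n_original))
  if (!is.null(x$asr))
    cat(sprintf("  asr: clean reference %.1f%%, reconstructed %.1f%%, %d window(s) dropped\n",
                100 * x$asr$clean_fraction,
                100 * x$asr$reconstructed_fraction, nrow(x$asr$dropped)))
  if (!is.null(x$filter))
    cat(sprintf("  filter: %.1f Hz cutoff (%.0f s session)\n",
                x$filter$cutoff_hz, x$filter$duration_s))
  if (!is.null(x$votes))
    cat(sprintf("  ics: %d/%d retained as brain\n",
                sum(x$votes$retained), nrow(x$votes)))
  invisible(x)
}

#' @export
print.eegcleanse_result <- function(x, ...) {
  cat(sprintf("<eegcleanse_result> status: %s%s\n", x$status,
              if (x$status == "excluded")
                sprintf(" (at %s)", x$excluded_at) else ""))
  print(x$report)
  invisible(x)
}

#' Tidy per-IC trace of a pipeline result
#'
#' @param x An `eegcleanse_result`.
#' @param ... Unused.
#' @return The per-IC vote tibble (one row per IC x version), or an empty
#'   tibble when the session was excluded before voting.
#' @export
tidy.eegcleanse_result <- function(x, ...) {
  if (is.null(x$report$votes)) return(tibble())
  tidy(x$report$votes)
}

#' One-row summary of a pipeline result
#'
#' @param x An `eegcleanse_result`.
#' @param ... Unused.
#' @return A one-row tibble with channel retention, ASR fractions, IC counts
#'   and the final status.
#' @export
glance.eegcleanse_result <- function(x, ...) {
  r <- x$report
  tibble(
    status = x$status,
    excluded_at = x$excluded_at,
    n_channels_original = r$channels$n_original %||% NA_integer_,
    n_channels_retained = r$channels$n_retained %||% NA_integer_,
    channel_retention_pct = if (!is.null(r$channels))
      100 * r$channels$n_retained / r$channels$n_original else NA_real_,
    clean_reference_pct = if (!is.null(r$asr))
      100 * r$asr$clean_fraction else NA_real_,
    reconstructed_pct = if (!is.null(r$asr))
      100 * r$asr$reconstructed_fraction else NA_real_,
    cutoff_hz = r$filter$cutoff_hz %||% NA_real_,
    n_ics = if (!is.null(r$votes)) nrow(r$votes) else NA_integer_,
    n_brain_ics_retained = if (!is.null(r$votes))
      sum(r$votes$retained) else NA_integer_,
    ic_retention_pct = if (!is.null(r$votes))
      100 * mean(r$votes$retained) else NA_real_)
}

#' Serialize a cleaning report to JSON
#'
#' @param report A `cleaning_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  out <- list(
    channels = if (!is.null(report$channels)) list(
      n_original = report$channels$n_original,
      n_after_impedance = report$channels$n_after_impedance,
      n_retained = report$channels$n_retained,
      status = report$channels$status,
      verdicts = dplyr::mutate(report$channels$verdicts,
                               reasons = vapply(.data$reasons, paste, "",
                                                collapse = ","))),
    asr = report$asr,
    filter = report$filter,
    ica = report$ica,
    votes = if (!is.null(report$votes))
      dplyr::mutate(report$votes,
                    brain_p = vapply(.data$brain_p, paste, "",
                                     collapse = ",")),
    ic_summary = report$ic_summary,
    reconstruction = report$reconstruction)
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
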