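# Trial validity gating, saccade selection, the early/late error taxonomy,
# saccade metrics and per-subject aggregation.

# saccade events with onset strictly after `lo` and at or before `hi`
saccades_in <- function(events, lo, hi) {
  events[events$kind == "saccade" & events$onset_ms > lo &
           events$onset_ms <= hi, , drop = FALSE]
}

# TRUE when no saccade or gap event overlaps [onset - clean_ms, onset),
# excluding the saccade starting exactly at `onset`
clean_history <- function(events, onset, clean_ms) {
  lo <- onset - clean_ms
  other <- events[events$kind %in% c("saccade", "gap"), , drop = FALSE]
  other <- other[other$onset_ms != onset | other$kind != "saccade", ,
                 drop = FALSE]
  !any(other$onset_ms < onset & other$offset_ms > lo)
}

#' Check pre-flash trial validity
#'
#' A trial enters analysis only if, throughout the window ending at target
#' flash onset, every sample is valid (no blink or gap), no saccade event
#' overlaps the window, and the horizontal gaze position stays within the
#' centre band (+/- `center_band_px` pixels, compared in degrees). The first
#' violated condition is reported, checked in the order blink, saccade,
#' off-centre.
#'
#' @param trial One row of a [trial_schedule()].
#' @param events An `event_list` for the session.
#' @param trace The session's `cyclopean_trace`.
#' @param geom A [screen_geometry()].
#' @param center_band_px Half-width of the permitted centre band in pixels.
#' @param preflash_window_ms Length of the checked window before flash onset.
#' @return A list with `valid` (logical) and `reason` (`NA`, "blink",
#'   "saccade" or "off_center").
#' @export
validate_trial <- function(trial, events, trace, geom = screen_geometry(),
                           center_band_px = 100, preflash_window_ms = 60) {
  flash <- trial$trial_start_ms + trial$flash_on_ms
  lo <- flash - preflash_window_ms
  # window [lo, flash) on the uniform time grid
  i1 <- findInterval(lo - 1e-9, trace$time_ms) + 1L
  i2 <- findInterval(flash - 1e-9, trace$time_ms)
  idx <- if (i2 >= i1) i1:i2 else integer(0)
  if (any(!trace$valid[idx])) {
    return(list(valid = FALSE, reason = "blink"))
  }
  sac <- events[events$kind == "saccade", , drop = FALSE]
  if (any(sac$onset_ms < flash & sac$offset_ms > lo)) {
    return(list(valid = FALSE, reason = "saccade"))
  }
  band_deg <- pixel_to_degree(center_band_px, geom)
  if (any(abs(trace$x_deg[idx]) > band_deg)) {
    return(list(valid = FALSE, reason = "off_center"))
  }
  list(valid = TRUE, reason = NA_character_)
}

#' Classify a fixation break during the memorisation phase
#'
#' Errors are saccades made after the eccentric target appears: the first
#' saccade (any direction, amplitude at least `min_amplitude_deg`) with onset
#' inside the memorisation phase (flash onset to the end of the memory
#' interval) is an early error when its onset is within
#' `early_late_boundary_ms` of flash onset, otherwise a late error.
#'
#' @inheritParams validate_trial
#' @param min_amplitude_deg Amplitude floor that keeps noise out of the error
#'   counts.
#' @param early_late_boundary_ms Early/late partition point (onset relative
#'   to flash onset; early is inclusive of the boundary).
#' @return A list with `type` ("early_error", "late_error" or "none"),
#'   `onset_ms` and `latency_ms` (onset minus flash onset), NA when none.
#' @export
classify_error <- function(trial, events, min_amplitude_deg = 1,
                           early_late_boundary_ms = 300) {
  spec_end <- trial$trial_start_ms + trial$go_ms     # end of memory interval
  flash <- trial$trial_start_ms + trial$flash_on_ms
  sac <- saccades_in(events, flash, spec_end)
  sac <- sac[sac$amplitude_deg >= min_amplitude_deg, , drop = FALSE]
  if (nrow(sac) == 0) {
    return(list(type = "none", onset_ms = NA_real_, latency_ms = NA_real_))
  }
  onset <- sac$onset_ms[1]
  lat <- onset - flash
  type <- if (lat <= early_late_boundary_ms) "early_error" else "late_error"
  list(type = type, onset_ms = onset, latency_ms = lat)
}

#' Select the memory-guided saccade of a trial
#'
#' Applies the first-saccade rule: only the first saccade with onset in the
#' reaction interval is considered. It is accepted when its amplitude is at
#' least `min_amplitude_deg`, its start lies within the centre band, it is
#' directed toward the cued side (optional), and the preceding
#' `clean_history_ms` contain no saccade or gap. If the first saccade fails
#' any criterion — or there is none — the trial is an omission; no fallback
#' saccade is taken.
#'
#' @inheritParams validate_trial
#' @inheritParams classify_error
#' @param clean_history_ms Required artefact-free interval before the
#'   saccade.
#' @param require_direction Require the saccade to move toward the cued side.
#' @return The accepted saccade event (one-row data frame) or `NULL`
#'   (omission).
#' @export
extract_mgs <- function(trial, events, geom = screen_geometry(),
                        center_band_px = 100, min_amplitude_deg = 1,
                        clean_history_ms = 100, require_direction = TRUE) {
  go <- trial$trial_start_ms + trial$go_ms
  confirm <- trial$trial_start_ms + trial$confirm_on_ms
  sac <- saccades_in(events, go, confirm)
  if (nrow(sac) == 0) return(NULL)
  s <- sac[1, ]
  band_deg <- pixel_to_degree(center_band_px, geom)
  ok <- s$amplitude_deg >= min_amplitude_deg &&
    abs(s$start_x_deg) <= band_deg &&
    (!require_direction ||
       sign(s$end_x_deg - s$start_x_deg) == trial$target_sign) &&
    clean_history(events, s$onset_ms, clean_history_ms)
  if (ok) s else NULL
}

#' Select the corrective visually guided saccade of a trial
#'
#' First-saccade rule inside the confirmation interval: the first saccade is
#' accepted when it is at least `min_amplitude_deg`, reduces the horizontal
#' distance to the (now visible) target, and has a clean preceding history.
#'
#' @inheritParams extract_mgs
#' @return The accepted saccade event (one-row data frame) or `NULL`.
#' @export
extract_corrective_vgs <- function(trial, events, geom = screen_geometry(),
                                   min_amplitude_deg = 1,
                                   clean_history_ms = 100) {
  confirm <- trial$trial_start_ms + trial$confirm_on_ms
  intertrial <- trial$trial_start_ms + trial$intertrial_on_ms
  target <- trial$target_sign * trial$eccentricity_deg
  sac <- saccades_in(events, confirm, intertrial)
  if (nrow(sac) == 0) return(NULL)
  s <- sac[1, ]
  toward <- abs(target - s$end_x_deg) < abs(target - s$start_x_deg)
  ok <- s$amplitude_deg >= min_amplitude_deg && toward &&
    clean_history(events, s$onset_ms, clean_history_ms)
  if (ok) s else NULL
}

#' Seven saccade metrics plus gain
#'
#' Latency (onset minus the interval anchor: the go signal for memory-guided
#' saccades, confirmation-dot onset for corrective saccades), amplitude,
#' duration, mean velocity, peak velocity, time to peak velocity, and gain =
#' amplitude / target amplitude x 100.
#'
#' @param sacc A one-row saccade event from an `event_list`.
#' @param target_amplitude_deg Amplitude the saccade should have covered
#'   (target eccentricity for a memory-guided saccade; the remaining distance
#'   to target for a corrective saccade). Must be non-zero.
#' @param anchor_ms Time of the interval anchor the latency is measured from.
#' @return A named list of the seven metrics (`latency_ms`, `amplitude_deg`,
#'   `duration_ms`, `mean_velocity_dps`, `peak_velocity_dps`,
#'   `time_to_peak_ms`, `gain_pct`).
#' @export
saccade_metrics <- function(sacc, target_amplitude_deg, anchor_ms) {
  if (!is.finite(target_amplitude_deg) || target_amplitude_deg == 0) {
    stop("target amplitude must be non-zero")
  }
  list(
    latency_ms = sacc$onset_ms - anchor_ms,
    amplitude_deg = sacc$amplitude_deg,
    duration_ms = sacc$duration_ms,
    mean_velocity_dps = sacc$mean_velocity_dps,
    peak_velocity_dps = sacc$peak_velocity_dps,
    time_to_peak_ms = sacc$time_to_peak_ms,
    gain_pct = 100 * sacc$amplitude_deg / abs(target_amplitude_deg)
  )
}

metric_names <- c("latency_ms", "amplitude_deg", "duration_ms",
                  "mean_velocity_dps", "peak_velocity_dps",
                  "time_to_peak_ms", "gain_pct")

#' Score every trial of a session
#'
#' Runs the preprocessing and event-detection chain on a recording, then
#' gates and classifies each scheduled trial: invalid (with reason), early or
#' late error, valid memory-guided saccade (with metrics and, when present,
#' the corrective visually guided saccade's metrics), or omission.
#'
#' @param recording A `gaze_recording`.
#' @param config A [pipeline_config()]; its preprocessing, ivt and trials
#'   blocks parameterise every stage.
#' @param subject Optional subject identifier carried into the output.
#' @return A data frame of class `trial_outcomes`, one row per trial:
#'   schedule fields, `valid`, `reason`, `outcome` ("valid_mgs",
#'   "early_error", "late_error", "omission", or NA when invalid),
#'   `error_latency_ms`, and the seven metrics for the memory-guided
#'   (`mgs_*`) and corrective (`vgs_*`) saccades.
#' @export
score_session <- function(recording, config = pipeline_config(),
                          subject = NA_character_) {
  stopifnot(inherits(recording, "gaze_recording"))
  trace <- preprocess_recording(recording,
                                config$preprocessing$gap_fill_ms,
                                config$preprocessing$velocity_window_ms)
  events <- detect_events(trace,
                          config$ivt$threshold_dps,
                          config$ivt$merge_time_ms,
                          config$ivt$merge_angle_deg,
                          config$ivt$min_fixation_ms)
  schedule <- recording$schedule
  geom <- recording$geometry
  tp <- config$trials

  out <- schedule[, c("trial", "side", "target_sign", "eccentricity_deg",
                      "eccentricity_class")]
  out$subject <- subject
  out$valid <- NA
  out$reason <- NA_character_
  out$outcome <- NA_character_
  out$error_latency_ms <- NA_real_
  for (pfx in c("mgs_", "vgs_")) {
    for (m in metric_names) out[[paste0(pfx, m)]] <- NA_real_
  }

  for (i in seq_len(nrow(schedule))) {
    trial <- schedule[i, ]
    v <- validate_trial(trial, events, trace, geom,
                        tp$center_band_px, tp$preflash_window_ms)
    out$valid[i] <- v$valid
    out$reason[i] <- v$reason
    if (!v$valid) next

    err <- classify_error(trial, events, tp$min_amplitude_deg,
                          tp$early_late_boundary_ms)
    if (err$type != "none") {
      out$outcome[i] <- err$type
      out$error_latency_ms[i] <- err$latency_ms
      next
    }

    mgs <- extract_mgs(trial, events, geom, tp$center_band_px,
                       tp$min_amplitude_deg, tp$clean_history_ms,
                       tp$require_direction)
    if (is.null(mgs)) {
      out$outcome[i] <- "omission"
      next
    }
    out$outcome[i] <- "valid_mgs"
    go <- trial$trial_start_ms + trial$go_ms
    mm <- saccade_metrics(mgs, trial$eccentricity_deg, go)
    for (m in metric_names) out[[paste0("mgs_", m)]][i] <- mm[[m]]

    vgs <- extract_corrective_vgs(trial, events, geom,
                                  tp$min_amplitude_deg, tp$clean_history_ms)
    if (!is.null(vgs)) {
      confirm <- trial$trial_start_ms + trial$confirm_on_ms
      target <- trial$target_sign * trial$eccentricity_deg
      vm <- saccade_metrics(vgs, target - vgs$start_x_deg, confirm)
      for (m in metric_names) out[[paste0("vgs_", m)]][i] <- vm[[m]]
    }
  }
  rownames(out) <- NULL
  class(out) <- c("trial_outcomes", "data.frame")
  out
}

#' Aggregate one subject's trial outcomes
#'
#' Computes the five session-level rates — `%MGS` over all session trials,
#' and `%CorrVGS`, `%EarlyErrorRate`, `%LateErrorRate`, `%TotalErrorRate`
#' over valid trials (the asymmetric denominators are deliberate) — plus the
#' mean and sample SD (n-1) of each of the seven metrics for memory-guided
#' and corrective saccades, separately for near and far targets. Subjects
#' with fewer valid trials than `min_valid_trials` are flagged `excluded`;
#' with zero valid trials the rates over valid trials are undefined (NA).
#'
#' @param outcomes A `trial_outcomes` table for one subject.
#' @param min_valid_trials Minimum number of valid trials for inclusion.
#' @param subject Subject identifier; defaults to the one in `outcomes`.
#' @return A one-row data frame of class `subject_summary`: `subject`,
#'   `n_trials`, `n_valid_trials`, `excluded`, `pct_mgs`, `pct_corr_vgs`,
#'   `pct_early_error`, `pct_late_error`, `pct_total_error`, and
#'   `{mgs,vgs}_{near,far}_{metric}_{mean,sd}` columns.
#' @export
summarize_subject <- function(outcomes, min_valid_trials = 7,
                              subject = NULL) {
  stopifnot(inherits(outcomes, "trial_outcomes"))
  if (is.null(subject)) subject <- outcomes$subject[1]
  n_trials <- nrow(outcomes)
  valid <- outcomes[!is.na(outcomes$valid) & outcomes$valid, , drop = FALSE]
  n_valid <- nrow(valid)

  n_mgs <- sum(valid$outcome == "valid_mgs", na.rm = TRUE)
  n_vgs <- sum(!is.na(valid$vgs_latency_ms))
  n_early <- sum(valid$outcome == "early_error", na.rm = TRUE)
  n_late <- sum(valid$outcome == "late_error", na.rm = TRUE)

  rate <- function(k, d) if (d > 0) 100 * k / d else NA_real_
  res <- data.frame(
    subject = subject,
    n_trials = n_trials,
    n_valid_trials = n_valid,
    excluded = n_valid < min_valid_trials,
    pct_mgs = rate(n_mgs, n_trials),
    pct_corr_vgs = rate(n_vgs, n_valid),
    pct_early_error = rate(n_early, n_valid),
    pct_late_error = rate(n_late, n_valid)
  )
  res$pct_total_error <- res$pct_early_error + res$pct_late_error

  for (type in c("mgs", "vgs")) {
    for (ecc in c("near", "far")) {
      sub <- valid[valid$eccentricity_class == ecc, , drop = FALSE]
      for (m in metric_names) {
        v <- sub[[paste0(type, "_", m)]]
        v <- v[!is.na(v)]
        base <- paste0(type, "_", ecc, "_", sub("_[^_]*$", "", m))
        res[[paste0(base, "_mean")]] <- if (length(v)) mean(v) else NA_real_
        res[[paste0(base, "_sd")]] <- if (length(v) > 1) stats::sd(v) else NA_real_
      }
    }
  }
  class(res) <- c("subject_summary", "data.frame")
  res
}

#' @export
print.trial_outcomes <- function(x, ...) {
  cat(sprintf("<trial_outcomes> %d trials: %d valid (%s)\n",
              nrow(x), sum(x$valid, na.rm = TRUE),
              paste(names(table(x$outcome)), table(x$outcome),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
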