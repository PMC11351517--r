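# Velocity-threshold (I-VT) event classification with the vendor-style
# post-filters: adjacent-fixation merging and a minimum fixation duration.

#' Classify a cyclopean trace into fixations, saccades and gaps
#'
#' Velocity-threshold identification: maximal runs of samples with windowed
#' angular velocity at or above the threshold become saccades, runs below it
#' become fixations, and runs where the position or the velocity is undefined
#' become gaps (undefined-velocity samples flanking true gaps terminate
#' events, which keeps segmentation conservative). A saccade's offset is the
#' time of its last above-threshold sample plus one sample period; its
#' kinematics are computed from the run: amplitude is the angular separation
#' of the start and end positions, mean velocity the mean of the per-sample
#' velocities, peak velocity their maximum, and time to peak the onset-to-
#' argmax interval.
#'
#' @param trace A `cyclopean_trace` with velocity (see [angular_velocity()]).
#' @param threshold_dps Velocity threshold in deg/s; samples exactly at the
#'   threshold are saccadic.
#' @return A data frame of class `event_list`, one row per event, with
#'   columns `kind` ("fixation", "saccade", "gap"), `onset_ms`, `offset_ms`,
#'   `duration_ms`, `start_x_deg`, `start_y_deg`, `end_x_deg`, `end_y_deg`,
#'   `centroid_x_deg`, `centroid_y_deg` (fixations), `amplitude_deg`
#'   (saccades), `mean_velocity_dps`, `peak_velocity_dps`, `time_to_peak_ms`.
#' @export
ivt_classify <- function(trace, threshold_dps = 30) {
  stopifnot(inherits(trace, "cyclopean_trace"))
  if (is.null(trace$velocity_dps)) {
    stop("trace has no velocity; run angular_velocity() first")
  }
  period <- attr(trace, "period_ms")
  state <- ifelse(!trace$valid | is.na(trace$velocity_dps), "gap",
                  ifelse(trace$velocity_dps >= threshold_dps,
                         "saccade", "fixation"))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  kind <- r$values
  n_ev <- length(kind)

  ev <- data.frame(
    kind = kind,
    onset_ms = trace$time_ms[starts],
    offset_ms = trace$time_ms[ends] + period,
    duration_ms = NA_real_,
    start_x_deg = trace$x_deg[starts], start_y_deg = trace$y_deg[starts],
    end_x_deg = trace$x_deg[ends], end_y_deg = trace$y_deg[ends],
    centroid_x_deg = NA_real_, centroid_y_deg = NA_real_,
    amplitude_deg = NA_real_,
    mean_velocity_dps = NA_real_, peak_velocity_dps = NA_real_,
    time_to_peak_ms = NA_real_
  )
  ev$duration_ms <- ev$offset_ms - ev$onset_ms
  for (k in seq_len(n_ev)) {
    idx <- starts[k]:ends[k]
    if (kind[k] == "fixation") {
      ev$centroid_x_deg[k] <- mean(trace$x_deg[idx])
      ev$centroid_y_deg[k] <- mean(trace$y_deg[idx])
    } else if (kind[k] == "saccade") {
      ev$amplitude_deg[k] <- sqrt(
        (ev$end_x_deg[k] - ev$start_x_deg[k])^2 +
          (ev$end_y_deg[k] - ev$start_y_deg[k])^2
      )
      v <- trace$velocity_dps[idx]
      ev$mean_velocity_dps[k] <- mean(v)
      ev$peak_velocity_dps[k] <- max(v)
      ev$time_to_peak_ms[k] <- trace$time_ms[idx[which.max(v)]] - ev$onset_ms[k]
    }
  }
  attr(ev, "period_ms") <- period
  class(ev) <- c("event_list", "data.frame")
  ev
}

#' Merge adjacent fixations
#'
#' Consecutive fixations separated (offset to onset) by at most `max_time_ms`
#' and with centroids at most `max_angle_deg` apart are merged into one
#' fixation; intervening short saccades or gaps are absorbed. The pass runs
#' left to right and is iterated until no merge applies. Merged centroids are
#' duration-weighted means of the originals.
#'
#' @param events An `event_list`.
#' @param max_time_ms,max_angle_deg Merge bounds (vendor defaults 75 ms and
#'   0.5 deg).
#' @return The merged `event_list`.
#' @export
merge_fixations <- function(events, max_time_ms = 75, max_angle_deg = 0.5) {
  stopifnot(inherits(events, "event_list"))
  repeat {
    fi <- which(events$kind == "fixation")
    if (length(fi) < 2) break
    merged <- FALSE
    for (k in seq_len(length(fi) - 1)) {
      i <- fi[k]; j <- fi[k + 1]
      gap <- events$onset_ms[j] - events$offset_ms[i]
      sep <- sqrt((events$centroid_x_deg[j] - events$centroid_x_deg[i])^2 +
                    (events$centroid_y_deg[j] - events$centroid_y_deg[i])^2)
      if (gap <= max_time_ms && sep <= max_angle_deg) {
        wi <- events$duration_ms[i]; wj <- events$duration_ms[j]
        events$centroid_x_deg[i] <-
          (events$centroid_x_deg[i] * wi + events$centroid_x_deg[j] * wj) /
          (wi + wj)
        events$centroid_y_deg[i] <-
          (events$centroid_y_deg[i] * wi + events$centroid_y_deg[j] * wj) /
          (wi + wj)
        events$offset_ms[i] <- events$offset_ms[j]
        events$end_x_deg[i] <- events$end_x_deg[j]
        events$end_y_deg[i] <- events$end_y_deg[j]
        events$duration_ms[i] <- events$offset_ms[i] - events$onset_ms[i]
        events <- events[-((i + 1):j), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  rownames(events) <- NULL
  events
}

#' Drop fixations shorter than a minimum duration
#'
#' Fixations shorter than `min_ms` are relabelled "unknown" so they no longer
#' count as fixations; the bound is inclusive (a fixation of exactly `min_ms`
#' is kept). Saccades and gaps are unaffected.
#'
#' @param events An `event_list`.
#' @param min_ms Minimum fixation duration in ms.
#' @return The filtered `event_list`.
#' @export
enforce_min_fixation <- function(events, min_ms = 60) {
  stopifnot(inherits(events, "event_list"))
  short <- events$kind == "fixation" & events$duration_ms < min_ms
  events$kind[short] <- "unknown"
  events
}

#' Full event detection chain
#'
#' [ivt_classify()], then [merge_fixations()], then
#' [enforce_min_fixation()].
#'
#' @param trace A velocity-annotated `cyclopean_trace`.
#' @param threshold_dps,merge_time_ms,merge_angle_deg,min_fixation_ms
#'   Stage parameters.
#' @return An `event_list`.
#' @export
detect_events <- function(trace, threshold_dps = 30, merge_time_ms = 75,
                          merge_angle_deg = 0.5, min_fixation_ms = 60) {
  enforce_min_fixation(
    merge_fixations(ivt_classify(trace, threshold_dps),
                    merge_time_ms, merge_angle_deg),
    min_fixation_ms
  )
}
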