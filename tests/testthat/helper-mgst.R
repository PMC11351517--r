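# Shared fixtures, all built in code.

default_geom <- screen_geometry()

# a profile that produces deterministic, artefact-free sessions
quiet_profile <- function(...) {
  base <- list(fixation_noise_sd = 0, blink_rate_per_trial = 0,
               interocular_offset_deg = 0, mgs_gain_sd = 0,
               mgs_latency_sd = 0, vgs_latency_sd = 0,
               early_error_prob = 0, late_error_prob = 0, omission_prob = 0)
  do.call(subject_profile, utils::modifyList(base, list(...)))
}

# independent minimum-jerk position profile for oracle computations
minjerk_oracle <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# hand-built cyclopean trace on a 4 ms grid (positions in degrees)
make_trace <- function(x_deg, y_deg = rep(0, length(x_deg)),
                       valid = rep(TRUE, length(x_deg)), period_ms = 4,
                       geom = default_geom, schedule = NULL) {
  trace <- data.frame(
    time_ms = (seq_along(x_deg) - 1) * period_ms,
    x_deg = ifelse(valid, x_deg, NA_real_),
    y_deg = ifelse(valid, y_deg, NA_real_),
    valid = valid
  )
  attr(trace, "geometry") <- geom
  attr(trace, "schedule") <- schedule
  attr(trace, "period_ms") <- period_ms
  class(trace) <- c("cyclopean_trace", "data.frame")
  trace
}

# hand-built gaze recording with both eyes at the given pixel positions
make_recording <- function(left_x, left_y, right_x = left_x,
                           right_y = left_y,
                           left_valid = rep(TRUE, length(left_x)),
                           right_valid = rep(TRUE, length(left_x)),
                           rate_hz = 250, geom = default_geom) {
  n <- length(left_x)
  samples <- data.frame(
    timestamp_ms = (seq_len(n) - 1) * 1000 / rate_hz,
    left_x_px = ifelse(left_valid, left_x, NA_real_),
    left_y_px = ifelse(left_valid, left_y, NA_real_),
    right_x_px = ifelse(right_valid, right_x, NA_real_),
    right_y_px = ifelse(right_valid, right_y, NA_real_),
    left_valid = left_valid,
    right_valid = right_valid,
    trial_index = 1L,
    interval_label = "fixation"
  )
  structure(list(samples = samples, geometry = geom, schedule = NULL,
                 sample_rate_hz = rate_hz),
            class = "gaze_recording")
}

# event list from raw fields, for post-filter tests
make_events <- function(kind, onset_ms, offset_ms,
                        centroid_x = rep(0, length(kind)),
                        centroid_y = rep(0, length(kind)), period_ms = 4) {
  ev <- data.frame(
    kind = kind, onset_ms = onset_ms, offset_ms = offset_ms,
    duration_ms = offset_ms - onset_ms,
    start_x_deg = centroid_x, start_y_deg = centroid_y,
    end_x_deg = centroid_x, end_y_deg = centroid_y,
    centroid_x_deg = ifelse(kind == "fixation", centroid_x, NA_real_),
    centroid_y_deg = ifelse(kind == "fixation", centroid_y, NA_real_),
    amplitude_deg = rep(NA_real_, length(kind)),
    mean_velocity_dps = rep(NA_real_, length(kind)),
    peak_velocity_dps = rep(NA_real_, length(kind)),
    time_to_peak_ms = rep(NA_real_, length(kind))
  )
  attr(ev, "period_ms") <- period_ms
  class(ev) <- c("event_list", "data.frame")
  ev
}
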