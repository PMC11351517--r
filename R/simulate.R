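# Synthetic gaze generation: minimum-jerk saccades placed on a session
# timeline, with AR(1) fixation noise, blinks as invalid-sample runs, and a
# ground-truth table for every trial.

# minimum-jerk position profile on normalised time tau in [0, 1]
minjerk_pos <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# truncated normal draws via inverse-CDF (exact, vectorised)
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# saccade kinematics from the main-sequence law; duration (s) from the
# minimum-jerk peak-factor relation Vpeak = 1.875 * A / T
saccade_kinematics <- function(amplitude_deg, profile) {
  vpeak <- profile$main_sequence_vmax *
    (1 - exp(-amplitude_deg / profile$main_sequence_c))
  duration_ms <- 1000 * 1.875 * amplitude_deg / vpeak
  list(peak_velocity_dps = vpeak, duration_ms = duration_ms,
       mean_velocity_dps = 1000 * amplitude_deg / duration_ms,
       time_to_peak_ms = duration_ms / 2)
}

#' Generate a single saccade waveform
#'
#' Produces a minimum-jerk position trajectory between two horizontal gaze
#' positions, sampled at the tracker rate, together with its analytic
#' kinematics. Peak velocity follows the main sequence
#' `vmax * (1 - exp(-A / c))`; because the minimum-jerk profile peaks at
#' `1.875 * A / T`, the duration is `T = 1.875 * A / Vpeak`. The velocity
#' profile is symmetric, so time to peak is half the duration.
#'
#' @param start_deg,end_deg Start and end gaze positions (deg); the amplitude
#'   `|end - start|` must be at least 0.1 deg.
#' @param profile A [subject_profile()] supplying the main-sequence
#'   parameters.
#' @param rate_hz Sampling rate.
#' @return A list with `time_ms` and `position_deg` (samples from onset to
#'   offset inclusive) and the analytic `amplitude_deg`, `duration_ms`,
#'   `peak_velocity_dps`, `mean_velocity_dps`, `time_to_peak_ms`.
#' @export
saccade_waveform <- function(start_deg, end_deg, profile = subject_profile(),
                             rate_hz = 250) {
  stopifnot(inherits(profile, "subject_profile"))
  amp <- abs(end_deg - start_deg)
  if (!is.finite(amp) || amp < 0.1) {
    stop("saccade amplitude must be at least 0.1 deg")
  }
  kin <- saccade_kinematics(amp, profile)
  period <- 1000 / rate_hz
  t <- seq(0, kin$duration_ms, by = period)
  pos <- start_deg + (end_deg - start_deg) * minjerk_pos(t / kin$duration_ms)
  c(list(time_ms = t, position_deg = pos, amplitude_deg = amp), kin)
}

#' Simulate one memory-guided saccade session
#'
#' Builds a full binocular gaze recording of a scheduled session with known
#' ground truth. Per trial the outcome is drawn from the profile
#' probabilities (a single uniform per trial, partitioned early / late /
#' omission / valid, so outcome sets are monotone in the probabilities under
#' a shared seed). Valid trials contain a memory-guided saccade in the
#' reaction interval (latency truncated-normal, >= 80 ms; amplitude = gain x
#' eccentricity toward the cued side) and, when the landing error is at least
#' 0.1 deg, a corrective visually guided saccade onto the target in the
#' confirmation interval. Error trials break fixation toward the flashed
#' target during the memorisation phase (early: 80-280 ms after flash onset;
#' late: 330 ms to the end of the memory interval), leaving a guard band
#' around the 300 ms early/late boundary so ground-truth labels stay
#' unambiguous at 4 ms sampling. Gaze is re-centred by a return saccade early
#' in the inter-trial interval. Per-eye AR(1) fixation noise and blinks
#' (runs of invalid samples in both eyes) are added last; the two eyes are
#' the cyclopean signal +/- half the interocular offset.
#'
#' @param schedule A [trial_schedule()].
#' @param profile A [subject_profile()].
#' @param geom A [screen_geometry()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list with `recording` (a `gaze_recording`: sample table plus
#'   geometry and schedule) and `ground_truth` (a `ground_truth` list with a
#'   per-trial table and a blink table).
#' @export
simulate_session <- function(schedule, profile = subject_profile(),
                             geom = screen_geometry(), seed = NULL) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(profile, "subject_profile"),
            inherits(geom, "screen_geometry"))
  spec <- attr(schedule, "spec")
  with_seed(seed, {
    period <- 1000 / spec$sample_rate_hz
    total_ms <- nrow(schedule) * spec$trial_duration_ms
    n <- round(total_ms / period)
    t <- (seq_len(n) - 1) * period
    x <- numeric(n)  # cyclopean horizontal position, deg

    # write one saccade segment and hold the landing position until
    # hold_end_ms (end of the current trial; later segments overwrite)
    place <- function(x, onset_ms, from_deg, to_deg, dur_ms, hold_end_ms) {
      i0 <- max(1L, ceiling(onset_ms / period) + 1L)
      i1 <- min(n, floor((onset_ms + dur_ms) / period) + 1L)
      if (i1 >= i0) {
        idx <- i0:i1
        x[idx] <- from_deg + (to_deg - from_deg) *
          minjerk_pos((t[idx] - onset_ms) / dur_ms)
      }
      i2 <- min(n, floor(hold_end_ms / period) + 1L)
      if (i2 > i1) x[(i1 + 1L):i2] <- to_deg
      x
    }

    gt <- data.frame(
      trial = schedule$trial, outcome = NA_character_,
      mgs_onset_ms = NA_real_, mgs_latency_ms = NA_real_,
      mgs_amplitude_deg = NA_real_, mgs_duration_ms = NA_real_,
      mgs_peak_velocity_dps = NA_real_,
      vgs_onset_ms = NA_real_, vgs_latency_ms = NA_real_,
      vgs_amplitude_deg = NA_real_,
      error_onset_ms = NA_real_, error_latency_ms = NA_real_
    )
    blinks <- data.frame(trial = integer(), onset_ms = numeric(),
                         offset_ms = numeric())
    invalid <- logical(n)

    p_e <- profile$early_error_prob
    p_l <- profile$late_error_prob
    p_o <- profile$omission_prob

    for (i in seq_len(nrow(schedule))) {
      tr <- schedule[i, ]
      t0 <- tr$trial_start_ms
      flash <- t0 + tr$flash_on_ms
      go <- t0 + tr$go_ms
      confirm <- t0 + tr$confirm_on_ms
      intertrial <- t0 + tr$intertrial_on_ms
      tend <- t0 + tr$trial_end_ms
      target <- tr$target_sign * tr$eccentricity_deg

      u <- stats::runif(1)
      outcome <- if (u < p_e) "early_error" else if (u < p_e + p_l) {
        "late_error"
      } else if (u < p_e + p_l + p_o) "omission" else "valid_mgs"
      gt$outcome[i] <- outcome
      cur <- 0

      if (outcome %in% c("early_error", "late_error")) {
        g <- rtnorm(1, profile$mgs_gain_mean, profile$mgs_gain_sd, 0.3, 1.5)
        land <- tr$target_sign * g * tr$eccentricity_deg
        kin <- saccade_kinematics(abs(land), profile)
        lat <- if (outcome == "early_error") {
          stats::runif(1, 80, 280)
        } else {
          stats::runif(1, 330, spec$target_flash_ms + spec$memory_ms -
                         kin$duration_ms - 30)
        }
        onset <- flash + lat
        x <- place(x, onset, 0, land, kin$duration_ms, tend)
        gt$error_onset_ms[i] <- onset
        gt$error_latency_ms[i] <- lat
        cur <- land
      } else if (outcome == "valid_mgs") {
        g <- rtnorm(1, profile$mgs_gain_mean, profile$mgs_gain_sd, 0.3, 1.5)
        land <- tr$target_sign * g * tr$eccentricity_deg
        kin <- saccade_kinematics(abs(land), profile)
        lat <- rtnorm(1, profile$mgs_latency_mean, profile$mgs_latency_sd,
                      80, spec$reaction_ms - kin$duration_ms - 30)
        onset <- go + lat
        x <- place(x, onset, 0, land, kin$duration_ms, tend)
        gt$mgs_onset_ms[i] <- onset
        gt$mgs_latency_ms[i] <- lat
        gt$mgs_amplitude_deg[i] <- abs(land)
        gt$mgs_duration_ms[i] <- kin$duration_ms
        gt$mgs_peak_velocity_dps[i] <- kin$peak_velocity_dps
        cur <- land

        resid <- target - land
        if (abs(resid) >= 0.1) {
          vkin <- saccade_kinematics(abs(resid), profile)
          vlat <- rtnorm(1, profile$vgs_latency_mean, profile$vgs_latency_sd,
                         80, spec$confirmation_ms - vkin$duration_ms - 30)
          vonset <- confirm + vlat
          x <- place(x, vonset, land, target, vkin$duration_ms, tend)
          gt$vgs_onset_ms[i] <- vonset
          gt$vgs_latency_ms[i] <- vlat
          gt$vgs_amplitude_deg[i] <- abs(resid)
          cur <- target
        }
      }

      if (abs(cur) >= 0.1) {  # re-centre during the inter-trial blank
        rkin <- saccade_kinematics(abs(cur), profile)
        x <- place(x, intertrial + 120, cur, 0, rkin$duration_ms, tend)
      }

      if (stats::runif(1) < profile$blink_rate_per_trial) {
        bdur <- rtnorm(1, profile$blink_duration_mean_ms,
                       profile$blink_duration_sd_ms, 20,
                       spec$trial_duration_ms / 2)
        bon <- t0 + stats::runif(1, 0, spec$trial_duration_ms - bdur)
        invalid[t >= bon & t < bon + bdur] <- TRUE
        blinks <- rbind(blinks, data.frame(trial = tr$trial, onset_ms = bon,
                                           offset_ms = bon + bdur))
      }
    }

    ar_noise <- function(n, sd, phi) {
      if (sd == 0) return(numeric(n))
      innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
      innov[1] <- stats::rnorm(1, 0, sd)
      as.numeric(stats::filter(innov, phi, method = "recursive"))
    }
    half <- profile$interocular_offset_deg / 2
    lx <- x - half + ar_noise(n, profile$fixation_noise_sd, profile$noise_ar)
    rx <- x + half + ar_noise(n, profile$fixation_noise_sd, profile$noise_ar)
    ly <- ar_noise(n, profile$fixation_noise_sd, profile$noise_ar)
    ry <- ar_noise(n, profile$fixation_noise_sd, profile$noise_ar)

    cx <- geom$width_px / 2
    cy <- geom$height_px / 2
    rel <- t - (findInterval(t, schedule$trial_start_ms) - 1) *
      spec$trial_duration_ms
    bounds <- c(0, schedule$flash_on_ms[1], schedule$memory_on_ms[1],
                schedule$go_ms[1], schedule$confirm_on_ms[1],
                schedule$intertrial_on_ms[1])
    labels <- c("fixation", "flash", "memory", "reaction", "confirmation",
                "intertrial")
    samples <- data.frame(
      timestamp_ms = t,
      left_x_px = cx + deg_to_px(lx, geom),
      left_y_px = cy + deg_to_px(ly, geom),
      right_x_px = cx + deg_to_px(rx, geom),
      right_y_px = cy + deg_to_px(ry, geom),
      left_valid = !invalid,
      right_valid = !invalid,
      trial_index = findInterval(t, schedule$trial_start_ms),
      interval_label = labels[findInterval(rel, bounds)]
    )
    samples$left_x_px[invalid] <- NA_real_
    samples$left_y_px[invalid] <- NA_real_
    samples$right_x_px[invalid] <- NA_real_
    samples$right_y_px[invalid] <- NA_real_

    recording <- structure(
      list(samples = samples, geometry = geom, schedule = schedule,
           sample_rate_hz = spec$sample_rate_hz),
      class = "gaze_recording"
    )
    ground_truth <- structure(list(trials = gt, blinks = blinks),
                              class = "ground_truth")
    list(recording = recording, ground_truth = ground_truth)
  })
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf(
    "<gaze_recording> %d samples at %g Hz (%.1f s), %d trials, %.1f%% valid\n",
    nrow(x$samples), x$sample_rate_hz,
    nrow(x$samples) / x$sample_rate_hz,
    max(x$samples$trial_index),
    100 * mean(x$samples$left_valid & x$samples$right_valid)
  ))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d trials: %s; %d blink(s)\n",
              nrow(x$trials),
              paste(names(table(x$trials$outcome)),
                    table(x$trials$outcome), sep = "=", collapse = ", "),
              nrow(x$blinks)))
  invisible(x)
}
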