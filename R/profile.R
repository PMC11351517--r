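#' Oculomotor profile of a simulated subject
#'
#' Collects the generating parameters for one subject's synthetic session:
#' saccade latency and gain distributions, the amplitude/peak-velocity main
#' sequence, fixation noise, outcome probabilities and blink behaviour.
#' Defaults describe a plausible older clinical cohort performing the task:
#' memory-guided saccades around 300 ms latency with hypometric gain ~0.9,
#' visually guided (corrective) saccades around 200 ms, a main sequence
#' saturating at 500 deg/s with amplitude constant 14 deg, and moderate
#' error/omission rates.
#'
#' @param mgs_latency_mean,mgs_latency_sd Memory-guided saccade latency (ms)
#'   from the go signal; draws are truncated at 80 ms.
#' @param mgs_gain_mean,mgs_gain_sd Saccade gain (amplitude / eccentricity);
#'   draws truncated to `[0.3, 1.5]`.
#' @param vgs_latency_mean,vgs_latency_sd Corrective saccade latency (ms) from
#'   confirmation-dot onset, truncated at 80 ms.
#' @param main_sequence_vmax Asymptotic peak velocity (deg/s).
#' @param main_sequence_c Main-sequence amplitude constant (deg): peak
#'   velocity = `vmax * (1 - exp(-amplitude / c))`.
#' @param fixation_noise_sd Stationary SD (deg) of per-eye fixation noise.
#' @param noise_ar AR(1) coefficient of the fixation noise; values near 1 give
#'   the slow drift/tremor mixture real trackers show rather than white noise.
#' @param early_error_prob,late_error_prob,omission_prob Per-trial outcome
#'   probabilities; the remainder is a valid memory-guided saccade. Their sum
#'   must not exceed 1.
#' @param blink_rate_per_trial Probability of one blink per trial.
#' @param blink_duration_mean_ms,blink_duration_sd_ms Blink (invalid-run)
#'   duration, truncated at 20 ms.
#' @param interocular_offset_deg Constant horizontal offset between the two
#'   eyes' reported positions (split symmetrically about the cyclopean signal).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(mgs_latency_mean = 300, mgs_latency_sd = 60,
                            mgs_gain_mean = 0.9, mgs_gain_sd = 0.1,
                            vgs_latency_mean = 200, vgs_latency_sd = 40,
                            main_sequence_vmax = 500, main_sequence_c = 14,
                            fixation_noise_sd = 0.3, noise_ar = 0.98,
                            early_error_prob = 0.1, late_error_prob = 0.15,
                            omission_prob = 0.05,
                            blink_rate_per_trial = 0.2,
                            blink_duration_mean_ms = 150,
                            blink_duration_sd_ms = 40,
                            interocular_offset_deg = 0.5) {
  p <- list(
    mgs_latency_mean = mgs_latency_mean, mgs_latency_sd = mgs_latency_sd,
    mgs_gain_mean = mgs_gain_mean, mgs_gain_sd = mgs_gain_sd,
    vgs_latency_mean = vgs_latency_mean, vgs_latency_sd = vgs_latency_sd,
    main_sequence_vmax = main_sequence_vmax,
    main_sequence_c = main_sequence_c,
    fixation_noise_sd = fixation_noise_sd, noise_ar = noise_ar,
    early_error_prob = early_error_prob, late_error_prob = late_error_prob,
    omission_prob = omission_prob,
    blink_rate_per_trial = blink_rate_per_trial,
    blink_duration_mean_ms = blink_duration_mean_ms,
    blink_duration_sd_ms = blink_duration_sd_ms,
    interocular_offset_deg = interocular_offset_deg
  )
  probs <- c(early_error_prob, late_error_prob, omission_prob,
             blink_rate_per_trial)
  if (any(!is.finite(unlist(p)))) stop("all profile fields must be finite")
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (early_error_prob + late_error_prob + omission_prob > 1) {
    stop("early_error_prob + late_error_prob + omission_prob must not exceed 1")
  }
  sds <- c(mgs_latency_sd, mgs_gain_sd, vgs_latency_sd, fixation_noise_sd,
           blink_duration_sd_ms)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (main_sequence_vmax <= 0 || main_sequence_c <= 0) {
    stop("main sequence parameters must be positive")
  }
  if (noise_ar < 0 || noise_ar >= 1) stop("noise_ar must lie in [0, 1)")
  structure(p, class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile> MGS latency %g+/-%g ms, gain %g+/-%g; Vmax %g deg/s (c = %g deg)\n",
    x$mgs_latency_mean, x$mgs_latency_sd, x$mgs_gain_mean, x$mgs_gain_sd,
    x$main_sequence_vmax, x$main_sequence_c
  ))
  cat(sprintf(
    "  P(early/late error, omission) = %.2f/%.2f, %.2f; blink rate %.2f/trial; noise %.2f deg\n",
    x$early_error_prob, x$late_error_prob, x$omission_prob,
    x$blink_rate_per_trial, x$fixation_noise_sd
  ))
  invisible(x)
}
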