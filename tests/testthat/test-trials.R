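# Scenario traces are built on the default single-trial timeline:
# flash at 1500 ms, go at 3000 ms, confirmation at 4500 ms.

trial1 <- trial_schedule(paradigm_spec(), seed = 1)[1, ]
n_samp <- 1925  # one 7700 ms trial at 250 Hz

# linear ramp "saccade" of constant velocity amp/dur
place_ramp <- function(x, onset_ms, from, to, dur_ms = 40, period = 4) {
  t <- (seq_along(x) - 1) * period
  idx <- which(t >= onset_ms & t < onset_ms + dur_ms)
  x[idx] <- from + (to - from) * (t[idx] - onset_ms) / dur_ms
  x[t >= onset_ms + dur_ms] <- to
  x
}

scenario <- function(x, valid = rep(TRUE, length(x))) {
  tr <- make_trace(x, valid = valid)
  list(trace = tr, events = detect_events(angular_velocity(tr)))
}

test_that("pre-flash validity gating reports the first violated condition", {
  # gaze parked at centre, no events -> valid
  s <- scenario(rep(0, n_samp))
  v <- validate_trial(trial1, s$events, s$trace)
  expect_true(v$valid)
  expect_true(is.na(v$reason))

  # gaze at +150 px during the window -> off-centre
  s <- scenario(rep(pixel_to_degree(150), n_samp))
  v <- validate_trial(trial1, s$events, s$trace)
  expect_false(v$valid)
  expect_equal(v$reason, "off_center")

  # +90 px is inside the band -> valid
  s <- scenario(rep(pixel_to_degree(90), n_samp))
  expect_true(validate_trial(trial1, s$events, s$trace)$valid)

  # blink overlapping the window -> blink
  bad <- rep(TRUE, n_samp); bad[360:368] <- FALSE  # 1440-1472 ms
  s <- scenario(rep(0, n_samp), valid = bad)
  v <- validate_trial(trial1, s$events, s$trace)
  expect_false(v$valid)
  expect_equal(v$reason, "blink")

  # saccade overlapping the window -> saccade
  x <- place_ramp(rep(0, n_samp), 1450, 0, 2)
  s <- scenario(x)
  v <- validate_trial(trial1, s$events, s$trace)
  expect_false(v$valid)
  expect_equal(v$reason, "saccade")
})

test_that("memorisation-phase fixation breaks split at the 300 ms boundary", {
  # break at flash + 250 ms -> early error
  s <- scenario(place_ramp(rep(0, n_samp), 1500 + 250, 0, 5))
  err <- classify_error(trial1, s$events)
  expect_equal(err$type, "early_error")
  expect_equal(err$latency_ms, 250, tolerance = 15)

  # break at flash + 400 ms -> late error
  s <- scenario(place_ramp(rep(0, n_samp), 1500 + 400, 0, 5))
  expect_equal(classify_error(trial1, s$events)$type, "late_error")

  # fixation held throughout -> none
  s <- scenario(rep(0, n_samp))
  expect_equal(classify_error(trial1, s$events)$type, "none")

  # sub-amplitude wobble is not an error
  s <- scenario(place_ramp(rep(0, n_samp), 1500 + 400, 0, 0.8, dur_ms = 12))
  expect_equal(classify_error(trial1, s$events)$type, "none")
})

test_that("the first-saccade rule selects or rejects the memory-guided saccade", {
  cue <- trial1$target_sign

  # single 9 deg saccade toward the cue at go + 250 ms, clean history
  s <- scenario(place_ramp(rep(0, n_samp), 3250, 0, cue * 9))
  mgs <- extract_mgs(trial1, s$events)
  expect_false(is.null(mgs))
  expect_equal(mgs$onset_ms - 3000, 250, tolerance = 15)
  expect_equal(mgs$amplitude_deg, 9, tolerance = 0.5)

  # first saccade of 0.8 deg -> omission, no fallback to the later 9 deg one
  x <- place_ramp(rep(0, n_samp), 3100, 0, cue * 0.8, dur_ms = 12)
  x <- place_ramp(x, 3400, cue * 0.8, cue * 9)
  s <- scenario(x)
  expect_null(extract_mgs(trial1, s$events))

  # saccade away from the cue -> omission unless direction is not required
  s <- scenario(place_ramp(rep(0, n_samp), 3250, 0, -cue * 9))
  expect_null(extract_mgs(trial1, s$events))
  expect_false(is.null(extract_mgs(trial1, s$events,
                                   require_direction = FALSE)))

  # start position outside the +-100 px band -> omission
  x0 <- rep(pixel_to_degree(150), n_samp)
  s <- scenario(place_ramp(x0, 3250, pixel_to_degree(150), 9))
  expect_null(extract_mgs(trial1, s$events))

  # a small saccade 50 ms earlier violates the clean-history rule (0.8 deg:
  # below the error floor but beyond the 0.5 deg fixation-merge bound)
  x <- place_ramp(rep(0, n_samp), 2950, 0, cue * 0.8, dur_ms = 12)
  x <- place_ramp(x, 3012, cue * 0.8, cue * 9)
  s <- scenario(x)
  expect_null(extract_mgs(trial1, s$events))
  expect_false(is.null(extract_mgs(trial1, s$events, clean_history_ms = 0)))

  # no saccade at all -> omission
  s <- scenario(rep(0, n_samp))
  expect_null(extract_mgs(trial1, s$events))
})

test_that("corrective saccades must reduce the distance to the target", {
  cue <- trial1$target_sign
  tgt <- cue * trial1$eccentricity_deg  # 10 or 18 deg

  # MGS lands short at 8/14.4 deg; corrective saccade at confirmation + 180
  land <- 0.8 * tgt
  x <- place_ramp(rep(0, n_samp), 3250, 0, land)
  x <- place_ramp(x, 4680, land, tgt, dur_ms = 30)
  s <- scenario(x)
  vgs <- extract_corrective_vgs(trial1, s$events)
  expect_false(is.null(vgs))
  expect_equal(vgs$onset_ms - 4500, 180, tolerance = 15)

  # gaze already on target: no confirmation-interval saccade -> absent
  x <- place_ramp(rep(0, n_samp), 3250, 0, tgt)
  s <- scenario(x)
  expect_null(extract_corrective_vgs(trial1, s$events))

  # a saccade moving away from the target is rejected
  x <- place_ramp(rep(0, n_samp), 3250, 0, land)
  x <- place_ramp(x, 4680, land, 0.5 * land, dur_ms = 30)
  s <- scenario(x)
  expect_null(extract_corrective_vgs(trial1, s$events))
})

test_that("saccade metrics follow their definitions and gain its formula", {
  sacc <- data.frame(onset_ms = 3250, offset_ms = 3298, duration_ms = 48,
                     amplitude_deg = 9, mean_velocity_dps = 187.5,
                     peak_velocity_dps = 351, time_to_peak_ms = 24)
  m <- saccade_metrics(sacc, 10, anchor_ms = 3000)
  expect_equal(m$latency_ms, 250)
  expect_equal(m$gain_pct, 90)
  expect_equal(saccade_metrics(sacc, 18, anchor_ms = 3000)$gain_pct, 50)
  expect_equal(saccade_metrics(sacc, 9, anchor_ms = 3000)$gain_pct, 100)
  expect_error(saccade_metrics(sacc, 0, anchor_ms = 3000), "non-zero")
})

test_that("time to peak of a symmetric saccade is half its duration", {
  sched <- trial_schedule(paradigm_spec(), seed = 91)
  sess <- simulate_session(sched, quiet_profile(mgs_gain_mean = 1),
                           default_geom, seed = 92)
  out <- score_session(sess$recording, pipeline_config(), "S")
  sel <- !is.na(out$mgs_time_to_peak_ms)
  expect_true(any(sel))
  expect_true(all(abs(out$mgs_time_to_peak_ms[sel] -
                        out$mgs_duration_ms[sel] / 2) <= 4))
})

test_that("noise-free sessions are recovered trial for trial", {
  sched <- trial_schedule(paradigm_spec(), seed = 93)
  prof <- quiet_profile(early_error_prob = 0.2, late_error_prob = 0.2,
                        omission_prob = 0.1, mgs_gain_mean = 0.85)
  sess <- simulate_session(sched, prof, default_geom, seed = 94)
  out <- score_session(sess$recording, pipeline_config(), "S")
  expect_true(all(out$valid))
  expect_equal(out$outcome, sess$ground_truth$trials$outcome)

  # latency and gain of accepted MGS match the generator
  gt <- sess$ground_truth$trials
  sel <- out$outcome == "valid_mgs"
  expect_equal(out$mgs_latency_ms[sel], gt$mgs_latency_ms[sel],
               tolerance = 0.1)
  expect_equal(out$mgs_gain_pct[sel],
               100 * gt$mgs_amplitude_deg[sel] / out$eccentricity_deg[sel],
               tolerance = 0.05)
  # every accepted MGS respects the floor and the start band
  expect_true(all(out$mgs_amplitude_deg[sel] >= 1))
})

test_that("sessions with realistic noise agree with ground truth on at least 95% of trials", {
  agree <- 0; total <- 0
  for (k in 1:5) {
    sched <- trial_schedule(paradigm_spec(), seed = 500 + k)
    prof <- subject_profile(fixation_noise_sd = 0.3,
                            blink_rate_per_trial = 0,
                            early_error_prob = 0.15, late_error_prob = 0.15,
                            omission_prob = 0.1)
    sess <- simulate_session(sched, prof, default_geom, seed = 600 + k)
    out <- score_session(sess$recording, pipeline_config(), "S")
    gt <- sess$ground_truth$trials$outcome
    ok <- !is.na(out$outcome)
    agree <- agree + sum(out$outcome[ok] == gt[ok])
    total <- total + sum(ok)
  }
  expect_gte(agree / total, 0.95)
})

test_that("subject summaries use the documented denominators and exclusion rule", {
  make_outcomes <- function(outcome, valid = rep(TRUE, length(outcome)),
                            vgs = rep(FALSE, length(outcome))) {
    n <- length(outcome)
    out <- data.frame(
      trial = seq_len(n), side = "left", target_sign = -1,
      eccentricity_deg = rep(c(10, 18), length.out = n),
      eccentricity_class = rep(c("near", "far"), length.out = n),
      subject = "S", valid = valid,
      reason = NA_character_,
      outcome = ifelse(valid, outcome, NA_character_),
      error_latency_ms = NA_real_
    )
    for (pfx in c("mgs_", "vgs_")) {
      for (m in c("latency_ms", "amplitude_deg", "duration_ms",
                  "mean_velocity_dps", "peak_velocity_dps",
                  "time_to_peak_ms", "gain_pct")) {
        out[[paste0(pfx, m)]] <- NA_real_
      }
    }
    out$mgs_latency_ms[out$outcome %in% "valid_mgs"] <- 300
    out$vgs_latency_ms[vgs & out$outcome %in% "valid_mgs"] <- 200
    class(out) <- c("trial_outcomes", "data.frame")
    out
  }

  # 40 trials, all valid, 30 MGS -> %MGS = 75 (denominator: all trials)
  oc <- make_outcomes(rep(c(rep("valid_mgs", 3), "omission"), 10))
  s <- summarize_subject(oc)
  expect_equal(s$pct_mgs, 75)
  expect_false(s$excluded)

  # 10 valid trials, 2 early + 3 late -> 20 / 30 / 50 over valid trials
  oc <- make_outcomes(c(rep("early_error", 2), rep("late_error", 3),
                        rep("valid_mgs", 5)),
                      valid = c(rep(TRUE, 10), rep(FALSE, 30)) )
  oc$outcome[11:40] <- NA
  s <- summarize_subject(oc)
  expect_equal(s$n_valid_trials, 10)
  expect_equal(s$pct_early_error, 20)
  expect_equal(s$pct_late_error, 30)
  expect_equal(s$pct_total_error, 50)
  expect_equal(s$pct_mgs, 100 * 5 / 40)

  # 6 valid trials -> excluded flag
  oc <- make_outcomes(rep("valid_mgs", 40),
                      valid = c(rep(TRUE, 6), rep(FALSE, 34)))
  expect_true(summarize_subject(oc)$excluded)

  # zero valid trials -> undefined valid-trial rates, flagged
  oc <- make_outcomes(rep("valid_mgs", 4), valid = rep(FALSE, 4))
  s <- summarize_subject(oc)
  expect_true(s$excluded)
  expect_true(is.na(s$pct_early_error))
  expect_equal(s$pct_mgs, 0)

  # %CorrVGS over valid trials
  oc <- make_outcomes(rep("valid_mgs", 8), vgs = rep(c(TRUE, FALSE), 4))
  expect_equal(summarize_subject(oc)$pct_corr_vgs, 50)
})

test_that("total error rate is exactly the sum of early and late for simulated subjects", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 6), paradigm_spec(),
                         default_geom, seed = 95)
  s <- coh$summaries
  ok <- !is.na(s$pct_total_error)
  expect_true(any(ok))
  expect_identical(s$pct_total_error[ok],
                   s$pct_early_error[ok] + s$pct_late_error[ok])
  expect_true(all(s$pct_mgs >= 0 & s$pct_mgs <= 100))
})
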