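test_that("saccade waveforms follow the main sequence analytically and numerically", {
  prof <- subject_profile(main_sequence_vmax = 500, main_sequence_c = 14)

  expect_error(saccade_waveform(0, 0, prof), "amplitude")
  expect_error(saccade_waveform(0, 0.05, prof), "amplitude")

  w <- saccade_waveform(0, 10, prof)
  expect_equal(w$peak_velocity_dps, 500 * (1 - exp(-10 / 14)),
               tolerance = 1e-12)
  expect_equal(w$peak_velocity_dps, 255.6, tolerance = 0.05)
  expect_equal(w$amplitude_deg, 10)
  expect_equal(w$time_to_peak_ms, w$duration_ms / 2)

  # tracker-rate samples, numerically differentiated, reach the analytic peak
  v_num <- max(abs(diff(w$position_deg)) / diff(w$time_ms)) * 1000
  expect_equal(v_num, w$peak_velocity_dps, tolerance = 0.05)

  # dense-grid oracle: the continuous profile peaks exactly at the closed form
  tau <- seq(0, 1, by = 1e-5)
  pos <- 10 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  v_dense <- max(diff(pos) / (1e-5 * w$duration_ms)) * 1000
  expect_equal(v_dense, w$peak_velocity_dps, tolerance = 1e-3)
})

test_that("forced outcomes produce the matching waveforms and labels", {
  sched <- trial_schedule(paradigm_spec(), seed = 5)

  early <- simulate_session(sched, quiet_profile(early_error_prob = 1),
                            default_geom, seed = 7)$ground_truth$trials
  expect_true(all(early$outcome == "early_error"))
  expect_true(all(early$error_latency_ms <= 300))
  expect_true(all(early$error_latency_ms > 0))

  omit <- simulate_session(sched, quiet_profile(omission_prob = 1),
                           default_geom, seed = 7)$ground_truth$trials
  expect_true(all(omit$outcome == "omission"))
  expect_true(all(is.na(omit$mgs_onset_ms)))

  late <- simulate_session(sched, quiet_profile(late_error_prob = 1),
                           default_geom, seed = 7)$ground_truth$trials
  expect_true(all(late$outcome == "late_error"))
  expect_true(all(late$error_latency_ms > 300))
  expect_true(all(late$error_latency_ms <= 1500))
})

test_that("ground-truth labels are consistent with the generated waveforms", {
  sched <- trial_schedule(paradigm_spec(), seed = 21)
  prof <- subject_profile(early_error_prob = 0.3, late_error_prob = 0.3,
                          omission_prob = 0.2, fixation_noise_sd = 0,
                          blink_rate_per_trial = 0, interocular_offset_deg = 0)
  sess <- simulate_session(sched, prof, default_geom, seed = 22)
  gt <- sess$ground_truth$trials
  s <- sess$recording$samples
  x <- pixel_to_degree(
    (s$left_x_px + s$right_x_px) / 2 - default_geom$width_px / 2, default_geom)

  for (i in seq_len(nrow(sched))) {
    t0 <- sched$trial_start_ms[i]
    go <- t0 + sched$go_ms[i]
    reaction <- s$timestamp_ms > go & s$timestamp_ms <= go + 1400
    moved <- any(abs(x[reaction]) > 1, na.rm = TRUE)
    if (gt$outcome[i] == "valid_mgs") {
      expect_true(moved)
      expect_gte(gt$mgs_latency_ms[i], 80)
    } else if (gt$outcome[i] == "omission") {
      expect_false(moved)
    } else {
      memo <- s$timestamp_ms > t0 + sched$flash_on_ms[i] &
        s$timestamp_ms <= go
      expect_true(any(abs(x[memo]) > 1, na.rm = TRUE))
    }
  }
})

test_that("outcome frequencies converge to the profile probabilities", {
  prof <- quiet_profile(early_error_prob = 0.2, late_error_prob = 0.15,
                        omission_prob = 0.1)
  outcomes <- character(0)
  for (k in 1:25) {  # 25 sessions x 40 trials = 1000 trials
    sched <- trial_schedule(paradigm_spec(), seed = 100 + k)
    gt <- simulate_session(sched, prof, default_geom,
                           seed = 200 + k)$ground_truth$trials
    outcomes <- c(outcomes, gt$outcome)
  }
  n <- length(outcomes)
  expect_equal(n, 1000)
  for (case in list(c("early_error", 0.2), c("late_error", 0.15),
                    c("omission", 0.1))) {
    p <- as.numeric(case[2])
    band <- 1.96 * sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(outcomes == case[1]) - p), band + 1e-12)
  }
})

test_that("raising the early-error probability enlarges the early set under a shared seed", {
  sched <- trial_schedule(paradigm_spec(), seed = 31)
  counts <- vapply(c(0.05, 0.2, 0.5), function(p) {
    gt <- simulate_session(sched, quiet_profile(early_error_prob = p),
                           default_geom, seed = 32)$ground_truth$trials
    sum(gt$outcome == "early_error")
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("blinks appear as invalid runs in both eyes", {
  sched <- trial_schedule(paradigm_spec(), seed = 41)
  prof <- quiet_profile(blink_rate_per_trial = 1)
  sess <- simulate_session(sched, prof, default_geom, seed = 42)
  blinks <- sess$ground_truth$blinks
  expect_equal(nrow(blinks), 40)
  s <- sess$recording$samples
  inside <- s$timestamp_ms >= blinks$onset_ms[1] &
    s$timestamp_ms < blinks$offset_ms[1]
  expect_true(all(!s$left_valid[inside] & !s$right_valid[inside]))
  expect_true(all(is.na(s$left_x_px[inside])))
})

test_that("cohort specs reject unmodelled parameters and infeasible structures", {
  expect_error(
    cohort_spec(rank_targets = data.frame(covariate = "age",
                                          parameter = "not_a_parameter",
                                          rho = 0.5)),
    "unmodelled"
  )
  expect_error(
    cohort_spec(rank_targets = data.frame(covariate = "nope",
                                          parameter = "late_error_prob",
                                          rho = 0.5)),
    "unknown covariate"
  )
  expect_error(
    cohort_spec(links = list(not_a_parameter = function(cov) cov$age)),
    "unmodelled"
  )
  # rank +-1 targets give a singular latent matrix and are rejected up front
  expect_error(
    cohort_spec(rank_targets = data.frame(covariate = "age",
                                          parameter = "late_error_prob",
                                          rho = 1)),
    "rho"
  )
  # contradictory strong targets: age highly correlated with two parameters
  # that are themselves uncorrelated is infeasible
  rt <- data.frame(covariate = c("age", "age"),
                   parameter = c("late_error_prob", "early_error_prob"),
                   rho = c(0.99, -0.99))
  expect_error(simulate_cohort(cohort_spec(n_subjects = 2, rank_targets = rt),
                               seed = 1),
               "positive semi-definite")
})

test_that("a null cohort shows no age/late-error association", {
  paradigm <- paradigm_spec()
  coh <- simulate_cohort(cohort_spec(n_subjects = 20), paradigm,
                         default_geom, seed = 51)
  rho <- suppressWarnings(
    cor(merge(coh$covariates, coh$summaries, by = "subject")$age,
        merge(coh$covariates, coh$summaries, by = "subject")$pct_late_error,
        method = "spearman", use = "complete.obs")
  )
  # null sampling band at n = 20: 1.96 / sqrt(n - 1)
  expect_lt(abs(rho), 1.96 / sqrt(19))
})

test_that("an induced rank correlation is recovered end to end", {
  rt <- data.frame(covariate = "age", parameter = "late_error_prob",
                   rho = 0.6)
  coh <- simulate_cohort(cohort_spec(n_subjects = 200, rank_targets = rt),
                         paradigm_spec(), default_geom, seed = 61)

  # the copula acts on the generating parameter: its rank correlation with
  # age must fall in the Fisher-z sampling band around the 0.6 target
  rho_par <- cor(coh$covariates$age, coh$profiles$late_error_prob,
                 method = "spearman")
  z_band <- 1.96 * 1.06 / sqrt(200 - 3)
  expect_gt(rho_par, tanh(atanh(0.6) - z_band))
  expect_lt(rho_par, tanh(atanh(0.6) + z_band))

  # the observable late-error rate adds binomial trial noise on top of the
  # between-subject spread; the expected correlation is attenuated by
  # lambda = sd(p) / sqrt(var(p) + mean(p (1 - p) / n_valid)) (classical
  # reliability attenuation), and the estimate must land in the Fisher band
  # around the attenuated target
  m <- merge(coh$covariates, coh$summaries, by = "subject")
  m <- m[!m$excluded & !is.na(m$pct_late_error), ]
  p_true <- coh$profiles$late_error_prob
  lambda <- stats::sd(p_true) /
    sqrt(stats::var(p_true) +
           mean(p_true * (1 - p_true) / coh$summaries$n_valid_trials))
  rho_obs <- cor(m$age, m$pct_late_error, method = "spearman")
  expect_gt(rho_obs, tanh(atanh(0.6 * lambda) - z_band))
  expect_lt(rho_obs, tanh(atanh(0.6 * lambda) + z_band))
  expect_lt(suppressWarnings(
    cor.test(m$age, m$pct_late_error, method = "spearman",
             exact = FALSE)$p.value), 1e-4)

  # the induced structure is documented in the output metadata
  expect_equal(attr(coh, "induced_correlations"), rt)
})
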