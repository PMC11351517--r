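# Synthetic cohorts: covariate tables with the study's variable names and
# per-subject oculomotor profiles, optionally rank-correlated through a
# Gaussian copula acting on the generating parameters (never on computed
# outputs, so downstream recovery is a genuine end-to-end check).

default_covariate_marginals <- function() {
  norm <- function(mean, sd, min, max, integer = FALSE) {
    list(dist = "norm", mean = mean, sd = sd, min = min, max = max,
         integer = integer)
  }
  list(
    age = norm(59.94, 10.88, 18, 80, integer = TRUE),
    gender = list(dist = "binary", prob = 0.774),   # 1 = male
    `MOTS-1` = norm(23, 4, 0, 30, integer = TRUE),
    `HDTSA-1` = norm(7, 4, 0, 21, integer = TRUE),
    `HDTSD-1` = norm(6, 4, 0, 21, integer = TRUE),
    `CLRES01-1` = norm(85, 30, 25, 300),
    `CLRES02-1` = norm(1, 1.2, 0, 10, integer = TRUE),
    `CLRES03-1` = norm(1.5, 1.5, 0, 10, integer = TRUE),
    `CLRES04-1` = norm(1, 1, 0, 10, integer = TRUE),
    `CLRES05-1` = norm(150, 45, 40, 400),
    `CLRES06-1` = norm(1, 1.2, 0, 10, integer = TRUE),
    `CLRES07-1` = norm(1, 1.2, 0, 10, integer = TRUE),
    `CLRES08-1` = norm(1.5, 1.5, 0, 10, integer = TRUE),
    `CLRES09-1` = norm(1, 1, 0, 10, integer = TRUE),
    `DGFRES-1` = norm(8, 2, 0, 16, integer = TRUE),
    `DGBRES-1` = norm(6, 2, 0, 14, integer = TRUE),
    `PSCNUM-1` = norm(40, 12, 0, 133, integer = TRUE),
    `PSSCNUM-1` = norm(22, 8, 0, 60, integer = TRUE),
    `PSSINUM-1` = norm(2, 2, 0, 20, integer = TRUE)
  )
}

# profile parameters that may vary across subjects, with their
# between-subject SDs and admissible ranges
default_parameter_spread <- function() {
  list(
    mgs_latency_mean = list(sd = 40, min = 120, max = 600),
    vgs_latency_mean = list(sd = 30, min = 100, max = 500),
    mgs_gain_mean = list(sd = 0.05, min = 0.4, max = 1.3),
    main_sequence_vmax = list(sd = 50, min = 250, max = 800),
    early_error_prob = list(sd = 0.08, min = 0, max = 0.6),
    late_error_prob = list(sd = 0.12, min = 0, max = 0.6),
    omission_prob = list(sd = 0.03, min = 0, max = 0.4)
  )
}

#' Specification of a synthetic cohort
#'
#' Bundles everything [simulate_cohort()] needs: the cohort size, marginal
#' distributions of the covariates (age, gender and the neuropsychological
#' scores, under the study's variable names), the baseline oculomotor
#' profile, the between-subject spread of the profile parameters allowed to
#' vary, target rank correlations between covariates and generating
#' parameters, and optional deterministic links.
#'
#' @param n_subjects Number of subjects.
#' @param covariates Named list of marginal specs (`dist = "norm"` with mean,
#'   sd, min, max, integer; or `dist = "binary"` with prob). Defaults cover
#'   the full covariate set of the task.
#' @param profile Baseline [subject_profile()]; per-subject parameters are
#'   drawn around its values.
#' @param parameter_spread Named list giving `sd`, `min`, `max` for each
#'   profile parameter that varies across subjects.
#' @param rank_targets Optional data frame with columns `covariate`,
#'   `parameter`, `rho`: target Spearman correlations, induced via a Gaussian
#'   copula (latent Pearson correlation `2 sin(pi rho / 6)`). Parameters must
#'   be present in `parameter_spread`; unknown names are rejected. An
#'   infeasible (non-positive-semi-definite) implied correlation matrix is
#'   rejected.
#' @param links Optional named list of functions `parameter = f(covariates)`
#'   applied after the copula draw; each receives the covariate data frame
#'   and returns the per-subject parameter values (clamped to the spread
#'   range). Useful to impose an exact functional relationship, e.g. a linear
#'   age effect on an error probability.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 62,
                        covariates = default_covariate_marginals(),
                        profile = subject_profile(),
                        parameter_spread = default_parameter_spread(),
                        rank_targets = NULL,
                        links = NULL) {
  stopifnot(inherits(profile, "subject_profile"), n_subjects >= 1)
  if (!is.null(rank_targets)) {
    stopifnot(is.data.frame(rank_targets),
              all(c("covariate", "parameter", "rho") %in% names(rank_targets)))
    bad_cov <- setdiff(rank_targets$covariate, names(covariates))
    if (length(bad_cov)) {
      stop("rank target(s) reference unknown covariate(s): ",
           paste(bad_cov, collapse = ", "))
    }
    bad_par <- setdiff(rank_targets$parameter, names(parameter_spread))
    if (length(bad_par)) {
      stop("rank target(s) reference unmodelled parameter(s): ",
           paste(bad_par, collapse = ", "))
    }
    if (any(abs(rank_targets$rho) >= 1)) stop("target rho must lie in (-1, 1)")
  }
  if (!is.null(links)) {
    bad <- setdiff(names(links), names(parameter_spread))
    if (length(bad)) {
      stop("link(s) reference unmodelled parameter(s): ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), covariates = covariates,
                 profile = profile, parameter_spread = parameter_spread,
                 rank_targets = rank_targets, links = links),
            class = "cohort_spec")
}

# latent correlation matrix over c(covariates, parameters); PSD check
build_latent_sigma <- function(cspec) {
  vars <- c(names(cspec$covariates), names(cspec$parameter_spread))
  k <- length(vars)
  sigma <- diag(k)
  dimnames(sigma) <- list(vars, vars)
  rt <- cspec$rank_targets
  if (!is.null(rt)) {
    for (i in seq_len(nrow(rt))) {
      r <- 2 * sin(pi * rt$rho[i] / 6)
      sigma[rt$covariate[i], rt$parameter[i]] <- r
      sigma[rt$parameter[i], rt$covariate[i]] <- r
    }
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("target correlation structure is not positive semi-definite")
  }
  sigma
}

marginal_quantile <- function(u, m) {
  if (m$dist == "binary") return(as.numeric(u > 1 - m$prob))
  plo <- stats::pnorm(m$min, m$mean, m$sd)
  phi <- stats::pnorm(m$max, m$mean, m$sd)
  x <- stats::qnorm(plo + u * (phi - plo), m$mean, m$sd)
  if (isTRUE(m$integer)) x <- round(x)
  pmin(pmax(x, m$min), m$max)
}

#' Simulate a cohort of synthetic subjects
#'
#' Draws per-subject covariates and oculomotor profiles from a
#' [cohort_spec()] (correlated through the Gaussian copula where targets are
#' set), simulates every subject's session with [simulate_session()], and —
#' by default — scores and summarises each session so the result is directly
#' usable by the statistical layer.
#'
#' @param cspec A [cohort_spec()].
#' @param paradigm A [paradigm_spec()]; each subject gets an independently
#'   shuffled schedule.
#' @param geom A [screen_geometry()].
#' @param seed Integer seed governing every draw.
#' @param config A [pipeline_config()] used for scoring.
#' @param keep `"summaries"` (default) scores each session as it is
#'   generated and keeps only outcome and summary tables; `"recordings"`
#'   additionally retains every `gaze_recording` and ground truth (memory
#'   heavy for large cohorts).
#' @return A list of class `mgst_cohort`: `covariates` (data frame with a
#'   `subject` column and the study variable names), `profiles` (per-subject
#'   generating parameters), `summaries` (one row per subject), `outcomes`
#'   (stacked per-trial table), and when requested `recordings` and
#'   `ground_truths`. The induced correlation structure is attached as
#'   attribute `"induced_correlations"`.
#' @export
simulate_cohort <- function(cspec = cohort_spec(),
                            paradigm = paradigm_spec(),
                            geom = screen_geometry(), seed = NULL,
                            config = pipeline_config(),
                            keep = c("summaries", "recordings")) {
  stopifnot(inherits(cspec, "cohort_spec"))
  keep <- match.arg(keep)
  with_seed(seed, {
    n <- cspec$n_subjects
    sigma <- build_latent_sigma(cspec)
    z <- matrix(stats::rnorm(n * ncol(sigma)), n) %*% chol(sigma)
    colnames(z) <- colnames(sigma)
    u <- stats::pnorm(z)

    covariates <- data.frame(subject = sprintf("S%03d", seq_len(n)),
                             check.names = FALSE)
    for (v in names(cspec$covariates)) {
      covariates[[v]] <- marginal_quantile(u[, v], cspec$covariates[[v]])
    }

    profiles <- data.frame(subject = covariates$subject)
    for (p in names(cspec$parameter_spread)) {
      sp <- cspec$parameter_spread[[p]]
      m <- list(dist = "norm", mean = cspec$profile[[p]], sd = sp$sd,
                min = sp$min, max = sp$max, integer = FALSE)
      profiles[[p]] <- marginal_quantile(u[, p], m)
    }
    if (!is.null(cspec$links)) {
      for (p in names(cspec$links)) {
        sp <- cspec$parameter_spread[[p]]
        profiles[[p]] <- pmin(pmax(cspec$links[[p]](covariates), sp$min),
                              sp$max)
      }
    }
    # keep outcome probabilities jointly feasible
    ptot <- profiles$early_error_prob + profiles$late_error_prob +
      profiles$omission_prob
    over <- ptot > 0.95
    if (any(over)) {
      for (p in c("early_error_prob", "late_error_prob", "omission_prob")) {
        profiles[[p]][over] <- profiles[[p]][over] * 0.95 / ptot[over]
      }
    }

    sub_seeds <- sample.int(.Machine$integer.max - 1, n)
    summaries <- vector("list", n)
    outcomes <- vector("list", n)
    recordings <- if (keep == "recordings") vector("list", n) else NULL
    truths <- if (keep == "recordings") vector("list", n) else NULL
    for (i in seq_len(n)) {
      prof <- cspec$profile
      for (p in names(cspec$parameter_spread)) prof[[p]] <- profiles[[p]][i]
      class(prof) <- "subject_profile"
      sched <- trial_schedule(paradigm, seed = sub_seeds[i])
      sess <- simulate_session(sched, prof, geom, seed = sub_seeds[i] + 1L)
      out <- score_session(sess$recording, config,
                           subject = covariates$subject[i])
      outcomes[[i]] <- out
      summaries[[i]] <- summarize_subject(out, config$trials$min_valid_trials)
      if (keep == "recordings") {
        recordings[[i]] <- sess$recording
        truths[[i]] <- sess$ground_truth
      }
    }
    res <- list(
      covariates = covariates,
      profiles = profiles,
      summaries = do.call(rbind, summaries),
      outcomes = do.call(rbind, outcomes)
    )
    if (keep == "recordings") {
      res$recordings <- recordings
      res$ground_truths <- truths
    }
    attr(res, "induced_correlations") <- cspec$rank_targets
    class(res) <- "mgst_cohort"
    res
  })
}

#' @export
print.mgst_cohort <- function(x, ...) {
  cat(sprintf("<mgst_cohort> %d subjects, %d excluded (<min valid trials)\n",
              nrow(x$summaries), sum(x$summaries$excluded)))
  invisible(x)
}
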