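# Readers and writers for the gaze TSV dialect, schedules, covariates and
# ground truth, plus the end-to-end pipeline orchestrator.

gaze_tsv_columns <- c("timestamp_ms", "left_x_px", "left_y_px", "right_x_px",
                      "right_y_px", "left_valid", "right_valid",
                      "trial_index", "interval_label")

#' Write a gaze recording as tab-separated samples
#'
#' One row per sample with columns `timestamp_ms`, `left_x_px`, `left_y_px`,
#' `right_x_px`, `right_y_px`, `left_valid`, `right_valid` (0/1),
#' `trial_index`, `interval_label`. Positions are written with four decimals,
#' invalid positions as `NA`, so writing a just-read canonical file
#' reproduces it byte for byte.
#'
#' @param rec A `gaze_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gaze_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "gaze_recording"))
  s <- rec$samples[, gaze_tsv_columns]
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
  out <- data.frame(
    timestamp_ms = sprintf("%g", s$timestamp_ms),
    left_x_px = fmt(s$left_x_px), left_y_px = fmt(s$left_y_px),
    right_x_px = fmt(s$right_x_px), right_y_px = fmt(s$right_y_px),
    left_valid = as.integer(s$left_valid),
    right_valid = as.integer(s$right_valid),
    trial_index = s$trial_index,
    interval_label = s$interval_label
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gaze recording from the tab-separated dialect
#'
#' Validates the header (every mandatory column must be present), drops and
#' counts malformed rows (non-finite timestamps), and enforces strictly
#' increasing, uniform timestamps.
#'
#' @param path Input file.
#' @param geometry A [screen_geometry()] attached to the recording.
#' @param schedule Optional [trial_schedule()] attached to the recording
#'   (required before scoring).
#' @param sample_rate_hz Sampling rate; inferred from the timestamps when
#'   `NULL`.
#' @return A `gaze_recording`.
#' @export
read_gaze_tsv <- function(path, geometry = screen_geometry(),
                          schedule = NULL, sample_rate_hz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(gaze_tsv_columns, names(s))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  s <- s[, gaze_tsv_columns]
  bad <- !is.finite(s$timestamp_ms)
  if (any(bad)) {
    message(sprintf("dropped %d malformed row(s)", sum(bad)))
    s <- s[!bad, , drop = FALSE]
  }
  dt <- diff(s$timestamp_ms)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * max(dt)) {
    stop("timestamps must be uniformly sampled")
  }
  s$left_valid <- as.logical(s$left_valid)
  s$right_valid <- as.logical(s$right_valid)
  if (is.null(sample_rate_hz)) sample_rate_hz <- 1000 / dt[1]
  structure(list(samples = s, geometry = geometry, schedule = schedule,
                 sample_rate_hz = sample_rate_hz),
            class = "gaze_recording")
}

#' Write / read a trial schedule as CSV
#'
#' @param schedule A [trial_schedule()].
#' @param path File path.
#' @return `path` / a `trial_schedule` (the generating [paradigm_spec()] is
#'   reattached from the boundary columns and `n_per_position`).
#' @export
write_trial_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "trial_schedule"))
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_schedule
#' @param sample_rate_hz Sampling rate recorded in the reattached spec.
#' @export
read_trial_schedule <- function(path, sample_rate_hz = 250) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "side", "target_sign", "eccentricity_deg",
            "eccentricity_class", "trial_start_ms", "flash_on_ms",
            "memory_on_ms", "go_ms", "confirm_on_ms", "intertrial_on_ms",
            "trial_end_ms")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("missing schedule column(s): ", paste(missing_cols, collapse = ", "))
  }
  eccs <- sort(unique(d$eccentricity_deg))
  spec <- paradigm_spec(
    central_fixation_ms = d$flash_on_ms[1],
    target_flash_ms = d$memory_on_ms[1] - d$flash_on_ms[1],
    memory_ms = d$go_ms[1] - d$memory_on_ms[1],
    reaction_ms = d$confirm_on_ms[1] - d$go_ms[1],
    confirmation_ms = d$intertrial_on_ms[1] - d$confirm_on_ms[1],
    intertrial_ms = d$trial_end_ms[1] - d$intertrial_on_ms[1],
    eccentricities_deg = eccs,
    sides = unique(d$side),
    trials_per_position = nrow(d) / (length(eccs) * length(unique(d$side))),
    sample_rate_hz = sample_rate_hz
  )
  attr(d, "spec") <- spec
  class(d) <- c("trial_schedule", "data.frame")
  d
}

#' Write / read a subject covariate table as CSV
#'
#' Column names follow the study's variable naming (`MOTS-1`, `HDTSA-1`,
#' `HDTSD-1`, `CLRES01-1` ... `CLRES09-1`, `DGFRES-1`, `DGBRES-1`,
#' `PSCNUM-1`, `PSSCNUM-1`, `PSSINUM-1`) and are preserved verbatim.
#'
#' @param covariates Data frame with a `subject` column.
#' @param path File path.
#' @return `path` / the covariate data frame.
#' @export
write_covariates <- function(covariates, path) {
  stopifnot("subject" %in% names(covariates))
  utils::write.csv(covariates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject" %in% names(d)) stop("covariate table needs a 'subject' column")
  d
}

#' Write / read session ground truth as JSON
#'
#' @param truth A `ground_truth` (see [simulate_session()]).
#' @param path File path.
#' @return `path` / a `ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       digits = NA, null = "null", na = "null",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$trials <- as.data.frame(raw$trials)
  raw$blinks <- as.data.frame(raw$blinks)
  structure(raw, class = "ground_truth")
}

# Table-2-style indicator names used in the exported summary CSV
summary_export_names <- function(nm) {
  map <- c(pct_mgs = "%MGS", pct_corr_vgs = "%CorrVGS",
           pct_early_error = "%EarlyErrorRate",
           pct_late_error = "%LateErrorRate",
           pct_total_error = "%TotalErrorRate")
  ifelse(nm %in% names(map), map[nm], nm)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) - process - summarise - stats and
#' optionally writes every artifact as CSV. Inputs are either an in-memory
#' [simulate_cohort()] result or paired gaze TSV / schedule CSV files plus a
#' covariate CSV. Deterministic given the configuration and its seed.
#'
#' @param config A [pipeline_config()].
#' @param cohort An `mgst_cohort`; when `NULL`, `gaze_paths` and
#'   `schedule_paths` are read instead.
#' @param gaze_paths,schedule_paths Parallel vectors of per-subject file
#'   paths (subject ids are the gaze file base names).
#' @param covariates Covariate data frame or CSV path; when present the
#'   statistical layer runs.
#' @param out_dir Optional output directory for `trial_outcomes.csv`,
#'   `subject_summaries.csv`, `correlations.csv`, `regression.csv` and
#'   `run_log.json`.
#' @return A list of class `mgst_run`: `outcomes`, `summaries`,
#'   `correlations` (or NULL), `regression` (or NULL) and `log` (config
#'   YAML, counts, rejection tally by reason, subjects excluded by the
#'   minimum-valid-trials rule).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         gaze_paths = NULL, schedule_paths = NULL,
                         covariates = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "mgst_config"))
  if (is.character(covariates)) covariates <- read_covariates(covariates)

  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "mgst_cohort"))
    outcomes <- cohort$outcomes
    summaries <- cohort$summaries
    if (is.null(covariates)) covariates <- cohort$covariates
  } else if (!is.null(gaze_paths) && length(gaze_paths)) {
    stopifnot(length(gaze_paths) == length(schedule_paths))
    outs <- vector("list", length(gaze_paths))
    sums <- vector("list", length(gaze_paths))
    for (i in seq_along(gaze_paths)) {
      sched <- read_trial_schedule(schedule_paths[i],
                                   config$paradigm$sample_rate_hz)
      rec <- read_gaze_tsv(gaze_paths[i], config$geometry, sched)
      sid <- sub("\\.[^.]*$", "", basename(gaze_paths[i]))
      outs[[i]] <- score_session(rec, config, subject = sid)
      sums[[i]] <- summarize_subject(outs[[i]],
                                     config$trials$min_valid_trials)
    }
    outcomes <- do.call(rbind, outs)
    summaries <- do.call(rbind, sums)
  } else {
    warning("no input recordings; returning empty outputs")
    empty <- data.frame()
    return(structure(list(outcomes = empty, summaries = empty,
                          correlations = NULL, regression = NULL,
                          log = list(n_subjects = 0)), class = "mgst_run"))
  }

  included <- summaries[!summaries$excluded, , drop = FALSE]
  correlations <- NULL
  regression <- NULL
  if (!is.null(covariates) && nrow(included) >= 3) {
    correlations <- correlate_all(included, covariates,
                                  method = config$stats$method,
                                  alpha = config$stats$alpha,
                                  adjust = config$stats$adjust)
    reg_predictors <- c("age", "gender", "MOTS-1", "HDTSA-1", "HDTSD-1",
                        "CLRES01-1", "CLRES02-1")
    merged <- merge(included, covariates, by = "subject")
    if (all(reg_predictors %in% names(merged)) &&
        nrow(merged) > length(reg_predictors) + 1) {
      regression <- fit_late_error_regression(merged,
                                              alpha = config$stats$alpha)
    }
  }

  reasons <- table(outcomes$reason[!is.na(outcomes$reason)])
  log <- list(
    config = config_to_yaml(config),
    n_subjects = nrow(summaries),
    n_trials = nrow(outcomes),
    n_valid_trials = sum(outcomes$valid, na.rm = TRUE),
    rejections_by_reason = as.list(reasons),
    subjects_excluded = summaries$subject[summaries$excluded]
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(outcomes, file.path(out_dir, "trial_outcomes.csv"),
                     row.names = FALSE)
    expsum <- summaries
    names(expsum) <- summary_export_names(names(expsum))
    utils::write.csv(expsum, file.path(out_dir, "subject_summaries.csv"),
                     row.names = FALSE)
    if (!is.null(correlations)) {
      utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                       row.names = FALSE)
    }
    if (!is.null(regression)) {
      utils::write.csv(regression$coefficients,
                       file.path(out_dir, "regression.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  structure(list(outcomes = outcomes, summaries = summaries,
                 correlations = correlations, regression = regression,
                 log = log),
            class = "mgst_run")
}

#' @export
print.mgst_run <- function(x, ...) {
  cat(sprintf("<mgst_run> %d subjects, %d trials (%d valid)\n",
              x$log$n_subjects, x$log$n_trials %||% 0,
              x$log$n_valid_trials %||% 0))
  invisible(x)
}
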