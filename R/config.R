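#' Pipeline configuration
#'
#' One nested list holding every tunable of the simulate-process-summarise-
#' stats chain. The defaults are the task's standard processing settings:
#' 75 ms gap fill, 20 ms velocity window, 30 deg/s velocity threshold, 75 ms /
#' 0.5 deg fixation merging, 60 ms minimum fixation, a +/-100 px centre band
#' checked for 60 ms before flash onset, 1 deg minimum saccade amplitude, a
#' 100 ms clean-history requirement, a 300 ms early/late boundary, at least 7
#' valid trials per subject, and Spearman correlations at alpha = 0.05 with
#' no multiplicity correction.
#'
#' @param geometry A [screen_geometry()].
#' @param paradigm A [paradigm_spec()].
#' @param preprocessing,ivt,trials,stats Named lists overriding individual
#'   defaults of each block.
#' @param seed Integer seed recorded with the run.
#' @return A nested list of class `mgst_config`.
#' @export
pipeline_config <- function(geometry = screen_geometry(),
                            paradigm = paradigm_spec(),
                            preprocessing = list(), ivt = list(),
                            trials = list(), stats = list(), seed = NULL) {
  merge_block <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown config field(s): ",
                          paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    geometry = geometry,
    paradigm = paradigm,
    preprocessing = merge_block(
      list(gap_fill_ms = 75, velocity_window_ms = 20), preprocessing),
    ivt = merge_block(
      list(threshold_dps = 30, merge_time_ms = 75, merge_angle_deg = 0.5,
           min_fixation_ms = 60), ivt),
    trials = merge_block(
      list(center_band_px = 100, preflash_window_ms = 60,
           min_amplitude_deg = 1, clean_history_ms = 100,
           early_late_boundary_ms = 300, min_valid_trials = 7,
           require_direction = TRUE), trials),
    stats = merge_block(
      list(method = "spearman", alpha = 0.05, adjust = "none"), stats),
    seed = seed
  )
  class(cfg) <- "mgst_config"
  cfg
}

#' @export
print.mgst_config <- function(x, ...) {
  cat("<mgst_config>\n")
  cat(sprintf("  preprocessing: gap fill %g ms, velocity window %g ms\n",
              x$preprocessing$gap_fill_ms, x$preprocessing$velocity_window_ms))
  cat(sprintf("  ivt: threshold %g deg/s, merge %g ms / %g deg, min fixation %g ms\n",
              x$ivt$threshold_dps, x$ivt$merge_time_ms, x$ivt$merge_angle_deg,
              x$ivt$min_fixation_ms))
  cat(sprintf("  trials: band %g px, pre-flash %g ms, min amplitude %g deg, boundary %g ms\n",
              x$trials$center_band_px, x$trials$preflash_window_ms,
              x$trials$min_amplitude_deg, x$trials$early_late_boundary_ms))
  cat(sprintf("  stats: %s, alpha %g, adjust %s\n",
              x$stats$method, x$stats$alpha, x$stats$adjust))
  invisible(x)
}

#' Serialise a configuration to YAML
#'
#' Round-trips losslessly through [config_from_yaml()].
#'
#' @param config An `mgst_config`.
#' @param path Optional file path; when `NULL` the YAML text is returned.
#' @return The YAML string, invisibly when written to a file.
#' @export
config_to_yaml <- function(config, path = NULL) {
  stopifnot(inherits(config, "mgst_config"))
  plain <- list(
    geometry = config$geometry[c("width_px", "height_px", "diagonal_mm",
                                 "viewing_distance_mm")],
    paradigm = unclass(config$paradigm)[
      c("central_fixation_ms", "target_flash_ms", "memory_ms", "reaction_ms",
        "confirmation_ms", "intertrial_ms", "eccentricities_deg", "sides",
        "trials_per_position", "sample_rate_hz")],
    preprocessing = config$preprocessing,
    ivt = config$ivt,
    trials = config$trials,
    stats = config$stats,
    seed = config$seed
  )
  txt <- yaml::as.yaml(plain)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a configuration from YAML
#'
#' @param path File path, or a YAML string produced by [config_to_yaml()].
#' @return An `mgst_config`.
#' @export
config_from_yaml <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    yaml::yaml.load(path)
  geometry <- do.call(screen_geometry, raw$geometry)
  paradigm <- do.call(paradigm_spec, raw$paradigm)
  pipeline_config(geometry = geometry, paradigm = paradigm,
                  preprocessing = raw$preprocessing %||% list(),
                  ivt = raw$ivt %||% list(),
                  trials = raw$trials %||% list(),
                  stats = raw$stats %||% list(),
                  seed = raw$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
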