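# Recording-level preprocessing: gap-fill interpolation, eye averaging into a
# cyclopean trace in degrees, and windowed angular velocity.

sample_period_ms <- function(rec) 1000 / rec$sample_rate_hz

#' Interpolate short gaps in a gaze recording
#'
#' Runs of invalid samples no longer than `max_gap_ms`, flanked by valid
#' samples on both sides, are linearly interpolated per eye and marked valid
#' (with an `*_interp` flag); longer runs, and runs touching the recording
#' edges, are left invalid. Idempotent.
#'
#' @param rec A `gaze_recording`.
#' @param max_gap_ms Longest gap (ms) that is filled; the vendor default is
#'   75 ms.
#' @return The recording with gaps filled and logical columns `left_interp`,
#'   `right_interp` added to the sample table.
#' @export
fill_gaps <- function(rec, max_gap_ms = 75) {
  stopifnot(inherits(rec, "gaze_recording"))
  s <- rec$samples
  period <- sample_period_ms(rec)
  for (eye in c("left", "right")) {
    vcol <- paste0(eye, "_valid")
    icol <- paste0(eye, "_interp")
    if (is.null(s[[icol]])) s[[icol]] <- FALSE
    r <- rle(!s[[vcol]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      a <- starts[k]; b <- ends[k]
      if (a == 1 || b == nrow(s)) next                 # edge gap: undefined
      if (r$lengths[k] * period > max_gap_ms) next      # too long
      for (coord in c("_x_px", "_y_px")) {
        col <- paste0(eye, coord)
        s[[col]][a:b] <- s[[col]][a - 1] +
          (s[[col]][b + 1] - s[[col]][a - 1]) *
          (s$timestamp_ms[a:b] - s$timestamp_ms[a - 1]) /
          (s$timestamp_ms[b + 1] - s$timestamp_ms[a - 1])
      }
      s[[vcol]][a:b] <- TRUE
      s[[icol]][a:b] <- TRUE
    }
  }
  rec$samples <- s
  rec
}

#' Average the two eyes into a cyclopean trace in degrees
#'
#' Where both eyes are valid the pixel positions are averaged; where exactly
#' one is valid that eye is used; where neither is valid the sample is
#' invalid. Positions are then converted to degrees of visual angle from the
#' screen centre via [pixel_to_degree()]. No smoothing is applied.
#'
#' @param rec A (typically gap-filled) `gaze_recording`.
#' @return A data frame of class `cyclopean_trace` with columns `time_ms`,
#'   `x_deg`, `y_deg`, `valid`; geometry, schedule and the sample period are
#'   attached as attributes.
#' @export
average_eyes <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  s <- rec$samples
  lw <- as.numeric(s$left_valid)
  rw <- as.numeric(s$right_valid)
  denom <- lw + rw
  valid <- denom > 0
  lx <- ifelse(s$left_valid, s$left_x_px, 0)
  ly <- ifelse(s$left_valid, s$left_y_px, 0)
  rx <- ifelse(s$right_valid, s$right_x_px, 0)
  ry <- ifelse(s$right_valid, s$right_y_px, 0)
  x_px <- ifelse(valid, (lx * lw + rx * rw) / pmax(denom, 1), NA_real_)
  y_px <- ifelse(valid, (ly * lw + ry * rw) / pmax(denom, 1), NA_real_)
  geom <- rec$geometry
  trace <- data.frame(
    time_ms = s$timestamp_ms,
    x_deg = NA_real_,
    y_deg = NA_real_,
    valid = valid
  )
  # offsets measured from the screen centre
  trace$x_deg[valid] <- pixel_to_degree(x_px[valid] - geom$width_px / 2, geom)
  trace$y_deg[valid] <- pixel_to_degree(y_px[valid] - geom$height_px / 2, geom)
  attr(trace, "geometry") <- geom
  attr(trace, "schedule") <- rec$schedule
  attr(trace, "period_ms") <- sample_period_ms(rec)
  class(trace) <- c("cyclopean_trace", "data.frame")
  trace
}

#' Windowed angular velocity of a cyclopean trace
#'
#' Velocity at a sample is the angular separation between the gaze positions
#' at the two ends of a centred window divided by the window duration,
#' reported in deg/s. The window spans `round(window_ms / period)` sampling
#' intervals (split as evenly as the grid allows around the sample); velocity
#' is undefined wherever any sample inside the window is invalid or the
#' window runs off the trace. Angular separation is the Euclidean distance in
#' (x, y) degree coordinates, which matches common velocity-threshold
#' implementations and differs negligibly from the exact visual angle below
#' 20 degrees.
#'
#' @param trace A `cyclopean_trace`.
#' @param window_ms Window length in ms; must span at least two sample
#'   periods.
#' @return The trace with columns `velocity_dps` (NA where undefined) added.
#' @export
angular_velocity <- function(trace, window_ms = 20) {
  stopifnot(inherits(trace, "cyclopean_trace"))
  period <- attr(trace, "period_ms")
  n_int <- round(window_ms / period)
  if (n_int < 2) {
    stop("velocity window must span at least 2 sample periods")
  }
  lo <- floor(n_int / 2)
  hi <- n_int - lo
  n <- nrow(trace)
  vel <- rep(NA_real_, n)
  i <- seq_len(n)
  ok <- i > lo & i + hi <= n
  # window fully valid: no invalid sample between i - lo and i + hi
  bad <- cumsum(!trace$valid)
  idx <- i[ok]
  win_ok <- (bad[idx + hi] - c(0, bad)[idx - lo]) == 0
  sel <- idx[win_ok]
  dx <- trace$x_deg[sel + hi] - trace$x_deg[sel - lo]
  dy <- trace$y_deg[sel + hi] - trace$y_deg[sel - lo]
  vel[sel] <- sqrt(dx^2 + dy^2) / (n_int * period / 1000)
  trace$velocity_dps <- vel
  trace
}

#' Preprocess a gaze recording into a velocity-annotated cyclopean trace
#'
#' Convenience chain: [fill_gaps()], [average_eyes()], [angular_velocity()].
#'
#' @param rec A `gaze_recording`.
#' @param gap_fill_ms,velocity_window_ms Parameters of the two stages.
#' @return A `cyclopean_trace` with velocity.
#' @export
preprocess_recording <- function(rec, gap_fill_ms = 75, velocity_window_ms = 20) {
  angular_velocity(average_eyes(fill_gaps(rec, gap_fill_ms)),
                   velocity_window_ms)
}
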