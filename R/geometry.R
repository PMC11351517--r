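#' Physical display geometry of an eye-tracking rig
#'
#' Describes the screen and viewing distance used for a memory-guided saccade
#' session and owns the pixel-to-visual-angle conversion. Defaults match a
#' 23-inch 16:9 panel at 1920 x 1080 viewed from 65 cm, the common screen-based
#' tracker arrangement. Square pixels are assumed, so the physical panel width
#' follows from the diagonal and the pixel aspect ratio.
#'
#' @param width_px,height_px Panel resolution in pixels.
#' @param diagonal_mm Physical panel diagonal in millimetres (23 in = 584.2 mm).
#' @param viewing_distance_mm Eye-to-screen distance in millimetres.
#'
#' @return An object of class `screen_geometry`: a list with the inputs plus
#'   the derived `physical_width_mm`, `physical_height_mm` and
#'   `pixel_pitch_mm` (mm per pixel).
#' @examples
#' geom <- screen_geometry()
#' pixel_to_degree(100, geom)  # ~2.34 degrees
#' @export
screen_geometry <- function(width_px = 1920L, height_px = 1080L,
                            diagonal_mm = 584.2, viewing_distance_mm = 650) {
  vals <- c(width_px, height_px, diagonal_mm, viewing_distance_mm)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all screen geometry fields must be finite and strictly positive")
  }
  aspect <- width_px / height_px
  physical_width_mm <- diagonal_mm * aspect / sqrt(1 + aspect^2)
  physical_height_mm <- physical_width_mm / aspect
  structure(
    list(
      width_px = as.integer(width_px),
      height_px = as.integer(height_px),
      diagonal_mm = diagonal_mm,
      viewing_distance_mm = viewing_distance_mm,
      physical_width_mm = physical_width_mm,
      physical_height_mm = physical_height_mm,
      pixel_pitch_mm = physical_width_mm / width_px
    ),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %d x %d px, diagonal %.1f mm, viewing distance %.0f mm\n",
    x$width_px, x$height_px, x$diagonal_mm, x$viewing_distance_mm
  ))
  cat(sprintf("  pixel pitch %.4f mm/px (square pixels)\n", x$pixel_pitch_mm))
  invisible(x)
}

#' Convert a pixel offset from screen centre to degrees of visual angle
#'
#' Positions (not extents) are converted, so the angle is the arctangent of
#' the off-centre physical distance over the viewing distance; the sign of the
#' offset is preserved. At task eccentricities (<= 20 deg) this differs from
#' the subtense form by well under 0.01 deg.
#'
#' @param offset_px Signed pixel offset(s) from the screen centre.
#' @param geom A [screen_geometry()].
#' @return Signed degrees of visual angle, same length as `offset_px`.
#' @seealso [degree_to_pixel()] for the inverse.
#' @export
pixel_to_degree <- function(offset_px, geom = screen_geometry()) {
  stopifnot(inherits(geom, "screen_geometry"))
  if (!is.numeric(offset_px) || any(!is.finite(offset_px))) {
    stop("offset_px must be finite numeric")
  }
  atan(offset_px * geom$pixel_pitch_mm / geom$viewing_distance_mm) * 180 / pi
}

#' Convert degrees of visual angle to a pixel offset from screen centre
#'
#' Exact inverse of [pixel_to_degree()] (up to floating point). Angles whose
#' horizontal projection falls beyond the panel edge are still converted but
#' flagged with a warning, since such a target cannot be displayed.
#'
#' @param angle_deg Signed visual angle(s), `abs(angle_deg) < 90`.
#' @param geom A [screen_geometry()].
#' @return Signed pixel offset(s), real-valued.
#' @export
degree_to_pixel <- function(angle_deg, geom = screen_geometry()) {
  stopifnot(inherits(geom, "screen_geometry"))
  if (!is.numeric(angle_deg) || any(!is.finite(angle_deg))) {
    stop("angle_deg must be finite numeric")
  }
  if (any(abs(angle_deg) >= 90)) {
    stop("angle_deg must satisfy |angle| < 90")
  }
  px <- deg_to_px(angle_deg, geom)
  off <- abs(px) > geom$width_px / 2
  if (any(off)) {
    warning(sprintf("%d target position(s) fall beyond the screen edge", sum(off)))
  }
  px
}

# conversion without the off-screen check, for gaze samples (which may
# legitimately leave the panel)
deg_to_px <- function(angle_deg, geom) {
  geom$viewing_distance_mm * tan(angle_deg * pi / 180) / geom$pixel_pitch_mm
}
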