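#' Display geometry for visual-angle conversion
#'
#' Describes the stimulus display: physical size (via the diagonal), pixel
#' resolution, refresh rate and viewing distance. Square pixels are assumed,
#' so the physical width/height follow from the diagonal and the resolution
#' aspect ratio. The refresh rate doubles as the time base of the stimulus
#' (one frame = `1/refresh_hz` s).
#'
#' @param diagonal_inches Screen diagonal in inches.
#' @param resolution_px Integer vector of length 2, horizontal and vertical
#'   resolution in pixels.
#' @param refresh_hz Refresh rate in Hz; also the stimulus sampling rate.
#' @param viewing_distance_cm Eye-to-screen distance in cm.
#' @return An object of class `display_geometry` with derived physical
#'   dimensions (`width_cm`, `height_cm`) and pixel pitch (`cm_per_px`).
#' @examples
#' geom <- display_geometry(24.5, c(1920, 1080), 240, 60)
#' screen_extent_degrees(geom)  # about 49 x 29 degrees
#' @export
display_geometry <- function(diagonal_inches = 24.5,
                             resolution_px = c(1920L, 1080L),
                             refresh_hz = 240,
                             viewing_distance_cm = 60) {
  if (length(resolution_px) != 2L || any(resolution_px <= 0))
    stop("invalid geometry: resolution_px must be two positive values")
  if (diagonal_inches <= 0 || refresh_hz <= 0 || viewing_distance_cm <= 0)
    stop("invalid geometry: diagonal, refresh rate and distance must be positive")
  diag_cm <- diagonal_inches * 2.54
  diag_px <- sqrt(sum(as.numeric(resolution_px)^2))
  width_cm <- diag_cm * resolution_px[1] / diag_px
  height_cm <- diag_cm * resolution_px[2] / diag_px
  structure(
    list(diagonal_inches = diagonal_inches,
         resolution_px = as.integer(resolution_px),
         refresh_hz = refresh_hz,
         viewing_distance_cm = viewing_distance_cm,
         width_cm = width_cm,
         height_cm = height_cm,
         cm_per_px = width_cm / resolution_px[1]),
    class = "display_geometry")
}

#' @export
print.display_geometry <- function(x, ...) {
  ext <- screen_extent_degrees(x)
  cat(sprintf(
    "Display: %.1f\" (%.1f x %.1f cm), %d x %d px @ %g Hz, %g cm viewing distance\n",
    x$diagonal_inches, x$width_cm, x$height_cm,
    x$resolution_px[1], x$resolution_px[2], x$refresh_hz,
    x$viewing_distance_cm))
  cat(sprintf("Angular extent: %.1f x %.1f degrees\n", ext[1], ext[2]))
  invisible(x)
}

#' Full angular extent of the screen in degrees
#'
#' Uses exact arctangent geometry (not the small-angle approximation): the
#' extent along each axis is twice the arctangent of half the physical
#' dimension over the viewing distance.
#'
#' @param geom A `display_geometry`.
#' @return Named numeric vector `c(horizontal, vertical)` in degrees.
#' @export
screen_extent_degrees <- function(geom) {
  stopifnot(inherits(geom, "display_geometry"))
  c(horizontal = 2 * atan2(geom$width_cm / 2, geom$viewing_distance_cm) * 180 / pi,
    vertical   = 2 * atan2(geom$height_cm / 2, geom$viewing_distance_cm) * 180 / pi)
}

#' Convert screen pixel coordinates to degrees of visual angle
#'
#' Center-origin, rightward and upward positive. Each pixel column/row maps
#' through its own local tangent, so the conversion is exact across the full
#' (wide) screen rather than linear in pixels. Pixel row indices increase
#' downward, hence the sign flip on y. NaN passes through.
#'
#' @param px,py Pixel coordinates (top-left origin, as recorded).
#' @param geom A `display_geometry`.
#' @return List with numeric vectors `x` and `y` in degrees.
#' @seealso [degrees_to_pixels()] for the inverse.
#' @export
pixels_to_degrees <- function(px, py, geom) {
  stopifnot(inherits(geom, "display_geometry"))
  cx <- (geom$resolution_px[1] - 1) / 2
  cy <- (geom$resolution_px[2] - 1) / 2
  d <- geom$viewing_distance_cm
  list(x = atan2((px - cx) * geom$cm_per_px, d) * 180 / pi,
       y = atan2(-(py - cy) * geom$cm_per_px, d) * 180 / pi)
}

#' Convert degrees of visual angle to screen pixel coordinates
#'
#' Inverse of [pixels_to_degrees()]; recovers pixels to floating tolerance.
#'
#' @param x_deg,y_deg Positions in degrees, center-origin, up-positive.
#' @param geom A `display_geometry`.
#' @return List with numeric vectors `px` and `py` (top-left origin).
#' @export
degrees_to_pixels <- function(x_deg, y_deg, geom) {
  stopifnot(inherits(geom, "display_geometry"))
  cx <- (geom$resolution_px[1] - 1) / 2
  cy <- (geom$resolution_px[2] - 1) / 2
  d <- geom$viewing_distance_cm
  list(px = cx + d * tan(x_deg * pi / 180) / geom$cm_per_px,
       py = cy - d * tan(y_deg * pi / 180) / geom$cm_per_px)
}

#' Convert a frame count to seconds
#'
#' @param n_frames Non-negative frame count.
#' @param refresh_hz Frame rate in Hz (default 240).
#' @return Duration in seconds, `n_frames / refresh_hz`.
#' @examples
#' frames_to_seconds(2, 240)  # 0.00833... s, i.e. 8.33 ms
#' @export
frames_to_seconds <- function(n_frames, refresh_hz = 240) {
  if (any(n_frames < 0)) stop("n_frames must be non-negative")
  n_frames / refresh_hz
}
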