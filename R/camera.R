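#' Camera intrinsic parameters
#'
#' Pinhole model of the wearable camera.  Square pixels are assumed; lens
#' distortion is not modeled.  All metric quantities are in millimeters on
#' the sensor (image) plane.
#'
#' @param focal_length_mm focal length in mm.
#' @param pixel_pitch_mm physical size of one (square) pixel in mm.
#' @param principal_point_px principal point `(cx, cy)` in pixels.
#' @param image_size_px image size `(width, height)` in pixels.
#'
#' @return An object of class `camera_intrinsics`.
#' @examples
#' cam <- camera_intrinsics(3, 0.003, c(640, 480), c(1280, 960))
#' @export
camera_intrinsics <- function(focal_length_mm, pixel_pitch_mm,
                              principal_point_px, image_size_px) {
  stopifnot(is.numeric(focal_length_mm), length(focal_length_mm) == 1,
            is.numeric(pixel_pitch_mm), length(pixel_pitch_mm) == 1,
            length(principal_point_px) == 2, length(image_size_px) == 2)
  if (focal_length_mm <= 0) stop("focal_length_mm must be positive", call. = FALSE)
  if (pixel_pitch_mm <= 0) stop("pixel_pitch_mm must be positive", call. = FALSE)
  if (any(image_size_px <= 0)) stop("image_size_px must be positive", call. = FALSE)
  if (principal_point_px[1] < 0 || principal_point_px[1] > image_size_px[1] ||
      principal_point_px[2] < 0 || principal_point_px[2] > image_size_px[2]) {
    stop("principal_point_px must lie within the image", call. = FALSE)
  }
  structure(
    list(focal_length_mm = as.numeric(focal_length_mm),
         pixel_pitch_mm = as.numeric(pixel_pitch_mm),
         principal_point_px = as.numeric(principal_point_px),
         image_size_px = as.numeric(image_size_px)),
    class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("Camera: f = %g mm, pixel pitch = %g mm, image %g x %g px, pp (%g, %g)\n",
              x$focal_length_mm, x$pixel_pitch_mm,
              x$image_size_px[1], x$image_size_px[2],
              x$principal_point_px[1], x$principal_point_px[2]))
  invisible(x)
}

#' Single ellipse observation in image-plane millimeters
#'
#' One frame's projection of the plate rim.  Coordinates are metric on the
#' sensor plane: the origin is the principal point, x points right, y
#' points down.  The orientation `theta` of the major axis is measured
#' counter-clockwise from +x and normalized to `[0, pi)`.
#'
#' @param cx,cy ellipse center in mm.
#' @param a,b semimajor and semiminor axes in mm (`a >= b > 0`).
#' @param theta major-axis angle in radians (any value; normalized).
#' @param frame non-negative integer frame index.
#'
#' @return An object of class `ellipse_obs`.
#' @export
ellipse_obs <- function(cx, cy, a, b, theta = 0, frame = 0L) {
  if (!is.finite(a) || !is.finite(b) || b <= 0) {
    stop("invalid observation: semi-axes must be positive", call. = FALSE)
  }
  if (a < b) {
    # tolerate tiny numerical inversions, otherwise swap with a quarter turn
    if (a < b * (1 - 1e-9)) {
      tmp <- a; a <- b; b <- tmp
      theta <- theta + pi / 2
    } else {
      a <- b
    }
  }
  structure(
    list(frame = as.integer(frame), cx = as.numeric(cx), cy = as.numeric(cy),
         a = as.numeric(a), b = as.numeric(b),
         theta = normalize_theta(as.numeric(theta))),
    class = "ellipse_obs")
}

#' @export
print.ellipse_obs <- function(x, ...) {
  cat(sprintf("Ellipse [frame %d]: center (%.4g, %.4g) mm, a = %.4g, b = %.4g mm, theta = %.2f deg\n",
              x$frame, x$cx, x$cy, x$a, x$b, rad2deg(x$theta)))
  invisible(x)
}

#' Convert pixel-space ellipse records to image-plane millimeters
#'
#' Applies the camera's pixel pitch and principal point so that downstream
#' geometry can work in metric sensor coordinates.  Accepts a data frame
#' with pixel columns `frame, center_x_px, center_y_px, a_px, b_px,
#' theta_deg` (the on-disk CSV layout) and returns one with mm columns
#' `frame, cx, cy, a, b, theta` (radians).
#'
#' @param raw data frame of pixel-space ellipse records.
#' @param cam a [camera_intrinsics()] object.
#' @return data frame of metric observations, one row per frame.
#' @export
pixels_to_image_plane <- function(raw, cam) {
  stopifnot(inherits(cam, "camera_intrinsics"))
  need <- c("frame", "center_x_px", "center_y_px", "a_px", "b_px", "theta_deg")
  if (!all(need %in% names(raw))) {
    stop("pixel records need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(raw$a_px)) || any(!is.finite(raw$b_px)) ||
      any(raw$a_px <= 0) || any(raw$b_px <= 0)) {
    stop("invalid observation: non-positive semi-axes in pixel records", call. = FALSE)
  }
  p <- cam$pixel_pitch_mm
  a <- pmax(raw$a_px, raw$b_px) * p
  b <- pmin(raw$a_px, raw$b_px) * p
  th <- deg2rad(raw$theta_deg) + ifelse(raw$a_px < raw$b_px, pi / 2, 0)
  data.frame(
    frame = as.integer(raw$frame),
    cx = (raw$center_x_px - cam$principal_point_px[1]) * p,
    cy = (raw$center_y_px - cam$principal_point_px[2]) * p,
    a = a, b = b,
    theta = normalize_theta(th))
}

#' Convert metric observations back to the pixel CSV layout
#'
#' Inverse of [pixels_to_image_plane()].
#'
#' @inheritParams pixels_to_image_plane
#' @param obs data frame of metric observations (`frame, cx, cy, a, b, theta`).
#' @return data frame in the pixel CSV layout.
#' @export
image_plane_to_pixels <- function(obs, cam) {
  p <- cam$pixel_pitch_mm
  data.frame(
    frame = as.integer(obs$frame),
    center_x_px = obs$cx / p + cam$principal_point_px[1],
    center_y_px = obs$cy / p + cam$principal_point_px[2],
    a_px = obs$a / p,
    b_px = obs$b / p,
    theta_deg = rad2deg(normalize_theta(obs$theta)))
}

# One-row data frame -> ellipse_obs
obs_row <- function(obs, i) {
  ellipse_obs(obs$cx[i], obs$cy[i], obs$a[i], obs$b[i], obs$theta[i], obs$frame[i])
}

as_obs_df <- function(e) {
  data.frame(frame = e$frame, cx = e$cx, cy = e$cy, a = e$a, b = e$b,
             theta = e$theta)
}
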