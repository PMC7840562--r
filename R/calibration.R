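# One-time per-location calibration: run the exact distance solver over a
# known-radius plate sequence and extract the trimmed distance range
# [D_lower, D_upper] from the histogram of per-frame distances.

#' Per-frame camera-to-plate distances for a known reference radius
#'
#' Applies [distance_from_ellipse()] to every frame.  Frames where the
#' solver fails are dropped with a warning rather than aborting the
#' calibration.
#'
#' @param obs data frame of metric observations (`frame, cx, cy, a, b,
#'   theta`), e.g. from [pixels_to_image_plane()].
#' @param cam a [camera_intrinsics()].
#' @param R_ref measured radius of the reference plate, mm.
#' @param tilt_band_deg passed to [distance_from_ellipse()].
#' @return data frame with columns `frame` and `D` (mm).
#' @export
compute_distance_series <- function(obs, cam, R_ref, tilt_band_deg = c(10, 80)) {
  stopifnot(nrow(obs) >= 1, R_ref > 0)
  D <- rep(NA_real_, nrow(obs))
  for (i in seq_len(nrow(obs))) {
    sol <- try(distance_from_ellipse(obs_row(obs, i), cam, R_ref, tilt_band_deg),
               silent = TRUE)
    if (!inherits(sol, "try-error")) D[i] <- sol$distance_D
  }
  bad <- is.na(D)
  if (any(bad)) {
    warning(sum(bad), " frame(s) dropped: distance solver failed (frames ",
            paste(obs$frame[bad], collapse = ", "), ")", call. = FALSE)
  }
  if (all(bad)) stop("calibration failure: no frame yielded a distance", call. = FALSE)
  data.frame(frame = obs$frame[!bad], D = D[!bad])
}

#' Trim a distance range via the sparse-extreme-bin histogram rule
#'
#' Builds an equal-width histogram of the distances and, in a single
#' pass, independently tests the lowest and the highest bin: if a bin's
#' count is less than half of the average frequency (`total / bins`), its
#' members are removed.  The returned range is the min and max of the
#' survivors.  The rule is applied once, not iterated.
#'
#' @param distances numeric vector of distances, mm (length >= 2).
#' @param bins number of histogram bins (>= 3); default 10.
#' @return `c(D_lower, D_upper)` in mm.
#' @export
trim_distance_range <- function(distances, bins = 10) {
  stopifnot(length(distances) >= 2, bins >= 3, all(is.finite(distances)))
  lo <- min(distances); hi <- max(distances)
  if (hi - lo <= 0) stop("zero-width error: all distances identical", call. = FALSE)
  width <- (hi - lo) / bins
  idx <- pmin(floor((distances - lo) / width), bins - 1)  # top edge -> last bin
  counts <- tabulate(idx + 1L, nbins = bins)
  thresh <- 0.5 * length(distances) / bins
  drop <- rep(FALSE, length(distances))
  if (counts[1] < thresh) drop <- drop | (idx == 0L)
  if (counts[bins] < thresh) drop <- drop | (idx == bins - 1L)
  keep <- distances[!drop]
  if (length(keep) == 0) stop("trim failure: no distances survive the histogram rule",
                              call. = FALSE)
  c(min(keep), max(keep))
}

#' One-time calibration of the camera-to-plate distance range
#'
#' Composition of [compute_distance_series()] and
#' [trim_distance_range()]: a meal recorded with a plate of known radius
#' at a fixed dining location yields the plausible distance range
#' `[D_lower, D_upper]` for all future meals at that location.
#'
#' @inheritParams compute_distance_series
#' @param bins histogram bins for range trimming; default 10.
#' @param camera_id,created_from provenance strings stored in the profile.
#' @return object of class `calibration_profile` with fields
#'   `reference_radius`, `D_lower`, `D_upper`, `n_frames_used`,
#'   `histogram_bins`, `camera_id`, `created_from`.
#' @export
calibrate <- function(obs, cam, R_ref, bins = 10, tilt_band_deg = c(10, 80),
                      camera_id = "", created_from = "") {
  series <- compute_distance_series(obs, cam, R_ref, tilt_band_deg)
  if (nrow(series) < 2) stop("calibration failure: need at least 2 usable frames",
                             call. = FALSE)
  rng <- if (nrow(series) == 2 || max(series$D) == min(series$D)) {
    range(series$D)
  } else {
    trim_distance_range(series$D, bins)
  }
  structure(list(reference_radius = R_ref,
                 D_lower = rng[1], D_upper = rng[2],
                 n_frames_used = nrow(series),
                 histogram_bins = as.integer(bins),
                 camera_id = camera_id, created_from = created_from),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf("Calibration profile: R_ref = %g mm, D range [%.1f, %.1f] mm from %d frames (%d bins)\n",
              x$reference_radius, x$D_lower, x$D_upper, x$n_frames_used,
              x$histogram_bins))
  invisible(x)
}
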