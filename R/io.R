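# Plain-text serialization: camera config and calibration profiles as
# JSON, ellipse sequences as CSV (pixels and degrees on disk, mm and
# radians in memory), line tables and estimation results as JSON.

#' Read a camera configuration from JSON
#'
#' Expected layout: `{"focal_length_mm", "pixel_pitch_mm",
#' "principal_point_px": [cx, cy], "image_size_px": [w, h]}`.
#'
#' @param path JSON file path.
#' @return a [camera_intrinsics()].
#' @export
read_camera_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_intrinsics(j$focal_length_mm, j$pixel_pitch_mm,
                    j$principal_point_px, j$image_size_px)
}

#' Write a camera configuration to JSON
#'
#' @param cam a [camera_intrinsics()].
#' @param path output path.
#' @export
write_camera_config <- function(cam, path) {
  jsonlite::write_json(
    list(focal_length_mm = cam$focal_length_mm,
         pixel_pitch_mm = cam$pixel_pitch_mm,
         principal_point_px = cam$principal_point_px,
         image_size_px = cam$image_size_px),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ellipse sequence CSV
#'
#' On-disk columns: `frame, center_x_px, center_y_px, a_px, b_px,
#' theta_deg`.  With `cam` supplied the result is converted to
#' image-plane mm and radians.
#'
#' @param path CSV file path.
#' @param cam optional [camera_intrinsics()] for metric conversion.
#' @return data frame (pixel layout, or metric when `cam` is given).
#' @export
read_ellipse_csv <- function(path, cam = NULL) {
  raw <- utils::read.csv(path)
  if (is.null(cam)) raw else pixels_to_image_plane(raw, cam)
}

#' Write an ellipse sequence CSV
#'
#' @param x pixel-layout data frame (e.g. an episode's `pixels`), or a
#'   metric data frame together with `cam`.
#' @param path output path.
#' @param cam optional [camera_intrinsics()]; when given, `x` is taken
#'   to be metric and converted to pixels first.
#' @export
write_ellipse_csv <- function(x, path, cam = NULL) {
  if (!is.null(cam)) x <- image_plane_to_pixels(x, cam)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a calibration profile to JSON
#'
#' @param profile a `calibration_profile`.
#' @param path output path.
#' @export
write_calibration_profile <- function(profile, path) {
  jsonlite::write_json(
    list(reference_radius_mm = profile$reference_radius,
         D_lower_mm = profile$D_lower, D_upper_mm = profile$D_upper,
         n_frames_used = profile$n_frames_used,
         histogram_bins = profile$histogram_bins,
         camera_id = profile$camera_id, created_from = profile$created_from),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration profile from JSON
#'
#' @param path JSON file path.
#' @return a `calibration_profile`.
#' @export
read_calibration_profile <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(reference_radius = j$reference_radius_mm,
                 D_lower = j$D_lower_mm, D_upper = j$D_upper_mm,
                 n_frames_used = j$n_frames_used,
                 histogram_bins = j$histogram_bins,
                 camera_id = j$camera_id %||% "",
                 created_from = j$created_from %||% ""),
            class = "calibration_profile")
}

#' Write a line table to JSON
#'
#' @param table a `line_table`.
#' @param path output path.
#' @export
write_line_table <- function(table, path) {
  jsonlite::write_json(
    list(radius_grid = table$radius_grid,
         gamma_band_deg = table$gamma_band_deg,
         distance_band_mm = table$distance_band_mm,
         N = table$n_pairs, f_mm = table$f_mm, seed = table$seed,
         lines = table$lines),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a line table from JSON
#'
#' @param path JSON file path.
#' @return a `line_table`.
#' @export
read_line_table <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(lines = as.data.frame(j$lines),
                 radius_grid = j$radius_grid,
                 gamma_band_deg = j$gamma_band_deg,
                 distance_band_mm = j$distance_band_mm,
                 n_pairs = as.integer(j$N), f_mm = j$f_mm,
                 seed = as.integer(j$seed)),
            class = "line_table")
}

#' Write a radius-estimation result to JSON
#'
#' @param est a `radius_estimate`.
#' @param path output path.
#' @param profile_file,table_file provenance strings recorded alongside.
#' @export
write_radius_estimate <- function(est, path, profile_file = "", table_file = "") {
  jsonlite::write_json(
    list(estimated_radius_mm = est$estimated_radius,
         gaussian = list(mean = est$gaussian_mean, sd = est$gaussian_sd,
                         amplitude = est$gaussian_amplitude),
         p_curve = unname(apply(est$p_curve, 1, function(r) c(r[1], r[2]),
                                simplify = FALSE)),
         n_frames_used = est$n_frames_used,
         n_outliers_removed = est$n_outliers_removed,
         profile_file = profile_file, table_file = table_file),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an episode's ellipse CSV and ground-truth sidecar
#'
#' Emits `<name>_ellipses.csv` (pixel layout) and `<name>_truth.json`
#' into `dir` -- the on-disk study layout consumed by
#' [read_study_dir()] and the command-line `evaluate` subcommand.
#'
#' @param ep an `episode` from [generate_episode()].
#' @param dir output directory (created if missing).
#' @param name file stem; default `"episode"`.
#' @return invisibly, the two paths written.
#' @export
write_episode <- function(ep, dir, name = "episode") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, "_ellipses.csv"))
  truth <- file.path(dir, paste0(name, "_truth.json"))
  write_ellipse_csv(ep$pixels, csv)
  gt <- ep$ground_truth
  jsonlite::write_json(
    list(true_radius_mm = gt$true_radius,
         distance_mm = gt$distance, gamma_rad = gt$gamma,
         outlier = gt$outlier),
    truth, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, truth))
}

#' Read a study directory of episode CSVs and truth sidecars
#'
#' Scans `dir` for `*_ellipses.csv` files with matching `*_truth.json`
#' sidecars and assembles a study object usable by
#' [cross_estimate_matrix()].
#'
#' @param dir study directory.
#' @param cam a [camera_intrinsics()].
#' @return a `study`-like list with `episodes` and `radii`.
#' @export
read_study_dir <- function(dir, cam) {
  csvs <- sort(list.files(dir, pattern = "_ellipses\\.csv$", full.names = TRUE))
  if (length(csvs) < 2) stop("study directory needs at least 2 episodes",
                             call. = FALSE)
  eps <- lapply(csvs, function(csv) {
    truth <- sub("_ellipses\\.csv$", "_truth.json", csv)
    if (!file.exists(truth)) stop("missing truth sidecar for ", csv, call. = FALSE)
    j <- jsonlite::read_json(truth, simplifyVector = TRUE)
    list(observations = read_ellipse_csv(csv, cam),
         ground_truth = list(true_radius = j$true_radius_mm,
                             distance = j$distance_mm,
                             gamma = j$gamma_rad, outlier = j$outlier))
  })
  structure(list(episodes = eps,
                 radii = vapply(eps, function(e) e$ground_truth$true_radius,
                                numeric(1))),
            class = "study")
}
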