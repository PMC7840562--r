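# Simplified single-variable model of the camera-to-plate relationship:
# with the optical axis through the plate center and the camera level but
# tilted down by gamma, the reciprocal semimajor axis of the image
# ellipse satisfies  1/a = (1/f) * sqrt((D/R)^2 - cos(gamma)^2).
# Monte-Carlo sampling over the tilt band followed by ordinary least
# squares yields, for each candidate radius, a linear model
# D ~ m * (1/a) + n.

#' Reciprocal semimajor axis under the simplified geometry
#'
#' Closed-form relationship between camera-to-plate distance and the
#' image ellipse's semimajor axis when the optical axis passes through
#' the plate center and the camera is level, tilted down by `gamma`.
#'
#' @param D camera-to-plate distance, mm (vectorized).
#' @param R plate radius, mm.
#' @param gamma tilt angle between the optical axis and the plate plane,
#'   radians in `(0, pi/2]` (vectorized).
#' @param f focal length, mm.
#' @return `1/a` in 1/mm, where `a` is the semimajor axis on the sensor.
#' @examples
#' # overhead view (gamma = 90 deg) reduces to the pinhole relation a = f R / D
#' 1 / simplified_inverse_a(400, 100, pi / 2, 3)  # = 0.75 mm
#' @export
simplified_inverse_a <- function(D, R, gamma, f) {
  stopifnot(all(D > 0), R > 0, f > 0, all(gamma > 0), all(gamma <= pi / 2 + 1e-12))
  val <- (D / R)^2 - cos(gamma)^2
  if (any(val <= 0)) {
    stop("domain error: D/R must exceed cos(gamma) (camera too close for the model)",
         call. = FALSE)
  }
  sqrt(val) / f
}

#' Simulate (1/a, D) pairs for one candidate radius
#'
#' Draws `n` independent pairs with the tilt angle uniform over
#' `gamma_band_deg` and the distance uniform over `distance_band_mm`,
#' evaluating the simplified model exactly for each draw.
#'
#' @param R candidate plate radius, mm.
#' @param f focal length, mm.
#' @param gamma_band_deg tilt band in degrees; default 20--70.
#' @param distance_band_mm distance band in mm; default 250--800.
#' @param n number of pairs; default 2000.
#' @param seed integer seed or `NULL`.
#' @return data frame with columns `inv_a` (1/mm), `D` (mm), `gamma` (rad).
#' @export
simulate_pairs <- function(R, f, gamma_band_deg = c(20, 70),
                           distance_band_mm = c(250, 800), n = 2000,
                           seed = NULL) {
  stopifnot(n >= 2, diff(gamma_band_deg) >= 0, diff(distance_band_mm) >= 0)
  # the whole band must respect the model's domain
  worst <- distance_band_mm[1] / R - cos(deg2rad(gamma_band_deg[1]))
  if (worst <= 0) {
    stop("configuration error: distance/tilt bands violate the model domain for R = ",
         R, call. = FALSE)
  }
  with_seed(seed, {
    gamma <- deg2rad(stats::runif(n, gamma_band_deg[1], gamma_band_deg[2]))
    D <- stats::runif(n, distance_band_mm[1], distance_band_mm[2])
    data.frame(inv_a = simplified_inverse_a(D, R, gamma, f), D = D, gamma = gamma)
  })
}

#' Least-squares line through (1/a, D) pairs
#'
#' Ordinary least squares of distance on reciprocal semimajor axis,
#' minimizing `sum((D_i - m/a_i - n)^2)`.
#'
#' @param pairs data frame with columns `inv_a` and `D`.
#' @return object of class `line_model`: list with `slope_m` (mm^2),
#'   `intercept_n` (mm), `rms_relative_residual` and optionally
#'   `radius_R_t`.
#' @export
fit_line <- function(pairs) {
  stopifnot(nrow(pairs) >= 2)
  x <- pairs$inv_a; y <- pairs$D
  if (max(x) - min(x) <= 1e-14 * max(abs(x))) {
    stop("singular fit: all 1/a values identical", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  n_i <- fit$coefficients[1]; m <- fit$coefficients[2]
  pred <- m * x + n_i
  structure(list(radius_R_t = NA_real_,
                 slope_m = unname(m), intercept_n = unname(n_i),
                 rms_relative_residual = sqrt(mean(((y - pred) / y)^2))),
            class = "line_model")
}

#' Predict camera-to-plate distance from a line model
#'
#' Evaluates `D = m/a + n` for a semimajor axis `a` in mm.
#'
#' @param line a `line_model` (see [fit_line()]) or one row of a line
#'   table's `lines` data frame.
#' @param a semimajor axis in mm (vectorized).
#' @return distance in mm.
#' @export
predict_distance <- function(line, a) {
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("invalid observation: semimajor axis must be positive", call. = FALSE)
  }
  m <- if (!is.null(line$slope_m)) line$slope_m else line$m
  n <- if (!is.null(line$intercept_n)) line$intercept_n else line$n
  m / a + n
}

#' Build the per-radius table of linear models
#'
#' For each candidate radius on the grid, simulates `n_pairs` (1/a, D)
#' pairs over the tilt and distance bands and fits the least-squares line
#' `D ~ m * (1/a) + n`.  Each radius uses an independently derived
#' sub-seed so the table is reproducible as a whole.
#'
#' @param f focal length, mm.
#' @param radius_grid `c(min, max, step)` in mm; default `c(30, 165, 1)`
#'   (136 radii).
#' @param gamma_band_deg tilt band in degrees; default 20--70.
#' @param distance_band_mm distance band in mm; default 250--800.  When a
#'   calibration profile is available, `c(0.8 * D_lower, 1.2 * D_upper)`
#'   is the recommended band (see [table_band_for_profile()]).
#' @param n_pairs simulated pairs per radius; default 2000.
#' @param seed integer seed.
#' @return object of class `line_table`: list with a `lines` data frame
#'   (columns `R_t`, `m`, `n`, `rms`) plus the generating configuration.
#' @export
build_line_table <- function(f, radius_grid = c(30, 165, 1),
                             gamma_band_deg = c(20, 70),
                             distance_band_mm = c(250, 800),
                             n_pairs = 2000, seed = 1L) {
  stopifnot(length(radius_grid) == 3, radius_grid[2] > radius_grid[1],
            radius_grid[3] > 0)
  grid <- seq(radius_grid[1], radius_grid[2], by = radius_grid[3])
  rows <- lapply(seq_along(grid), function(t) {
    p <- simulate_pairs(grid[t], f, gamma_band_deg, distance_band_mm,
                        n_pairs, seed = derive_seed(seed, t))
    ln <- fit_line(p)
    data.frame(R_t = grid[t], m = ln$slope_m, n = ln$intercept_n,
               rms = ln$rms_relative_residual)
  })
  structure(list(lines = do.call(rbind, rows),
                 radius_grid = as.numeric(radius_grid),
                 gamma_band_deg = as.numeric(gamma_band_deg),
                 distance_band_mm = as.numeric(distance_band_mm),
                 n_pairs = as.integer(n_pairs), f_mm = f,
                 seed = as.integer(seed)),
            class = "line_table")
}

#' @export
print.line_table <- function(x, ...) {
  cat(sprintf("Line table: %d radii in [%g, %g] mm (step %g), gamma %g-%g deg, D %g-%g mm, N = %d, seed %d\n",
              nrow(x$lines), x$radius_grid[1], x$radius_grid[2], x$radius_grid[3],
              x$gamma_band_deg[1], x$gamma_band_deg[2],
              x$distance_band_mm[1], x$distance_band_mm[2], x$n_pairs, x$seed))
  cat(sprintf("  slope m: %.1f .. %.1f mm^2; max RMS relative residual %.3f\n",
              min(x$lines$m), max(x$lines$m), max(x$lines$rms)))
  invisible(x)
}

# row of the lines data frame for a given radius (exact grid match)
table_line <- function(table, R_t) {
  i <- which(abs(table$lines$R_t - R_t) < 1e-9)
  if (length(i) != 1) stop("radius ", R_t, " not on the table grid", call. = FALSE)
  table$lines[i, ]
}

#' Recommended simulation distance band for a calibration profile
#'
#' Lines should be fit over the regime where they are evaluated; with a
#' calibrated range available the band extends it by 20% on both sides.
#'
#' @param profile a [calibration_profile].
#' @return `c(lower, upper)` in mm.
#' @export
table_band_for_profile <- function(profile) {
  c(0.8 * profile$D_lower, 1.2 * profile$D_upper)
}
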