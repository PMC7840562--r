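# Radius estimation for an unknown plate: robust outlier filtering of the
# ellipse sequence, pooled distances per candidate radius (line-model
# prediction plus exact cone inversion), the inclusion index P, and a
# Gaussian fit of the P-vs-R curve whose mean is the estimated radius.

#' Flag non-eating frames as outliers
#'
#' Sudden large changes in the ellipse center or orientation (reaching
#' for a remote drink, operating a remote control, ...) do not fit the
#' quasiperiodic eating model.  A frame is flagged when both its incoming
#' and outgoing frame-to-frame changes exceed a robust threshold
#' (median + k * MAD with absolute floors), i.e. the ellipse jumps away
#' and back.
#'
#' @param obs data frame of metric observations (>= 3 rows).
#' @param k MAD multiplier; default 4.
#' @param center_floor_mm absolute floor on the center-displacement
#'   threshold, mm on the sensor; default 0.2 (guards the MAD = 0 case of
#'   a perfectly steady sequence).
#' @param angle_floor_deg absolute floor on the orientation-change
#'   threshold; default 5 degrees.
#' @return list with `kept` (surviving rows, original order), `removed`
#'   (integer row indices flagged).  More than 50% flagged raises a
#'   warning; fewer than 3 survivors is an error.
#' @export
filter_outliers <- function(obs, k = 4, center_floor_mm = 0.2,
                            angle_floor_deg = 5) {
  n <- nrow(obs)
  stopifnot(n >= 3)
  disp <- sqrt(diff(obs$cx)^2 + diff(obs$cy)^2)          # length n - 1
  dth <- fold_angle_diff(diff(obs$theta))
  thr_c <- stats::median(disp) + max(k * stats::mad(disp), center_floor_mm)
  thr_t <- stats::median(dth) + max(k * stats::mad(dth), deg2rad(angle_floor_deg))
  jump <- (disp > thr_c) | (dth > thr_t)                 # jump[i]: i -> i+1 large
  flag <- rep(FALSE, n)
  if (n >= 3) {
    mid <- 2:(n - 1)
    flag[mid] <- jump[mid - 1] & jump[mid]
  }
  flag[1] <- jump[1] && !flag[2]
  flag[n] <- jump[n - 1] && !flag[n - 1]
  removed <- which(flag)
  if (length(removed) > n / 2) {
    warning("excessive outliers: more than half of the frames flagged", call. = FALSE)
  }
  if (n - length(removed) < 3) {
    stop("estimation failure: fewer than 3 frames survive outlier filtering",
         call. = FALSE)
  }
  list(kept = obs[!flag, , drop = FALSE], removed = removed)
}

#' Pooled distance set for one candidate radius
#'
#' Combines two per-frame distance estimates into one multiset, doubling
#' the number of data points: the line-model prediction `D = m/a + n` and
#' the exact cone-inversion distance for the candidate radius.
#' Duplicates are retained; solver failures are dropped with a warning.
#'
#' @param obs data frame of metric observations.
#' @param cam a [camera_intrinsics()].
#' @param line line model for `R_t` (see [fit_line()] / [table_line]).
#' @param R_t candidate radius, mm.
#' @param tilt_band_deg passed to [distance_from_ellipse()].
#' @return numeric vector of pooled distances (length up to `2 * nrow(obs)`).
#' @export
pooled_distances <- function(obs, cam, line, R_t, tilt_band_deg = c(10, 80)) {
  stopifnot(nrow(obs) >= 1)
  D1 <- predict_distance(line, obs$a)
  D2 <- rep(NA_real_, nrow(obs))
  for (i in seq_len(nrow(obs))) {
    sol <- try(distance_from_ellipse(obs_row(obs, i), cam, R_t, tilt_band_deg),
               silent = TRUE)
    if (!inherits(sol, "try-error")) D2[i] <- sol$distance_D
  }
  if (anyNA(D2)) {
    warning(sum(is.na(D2)), " frame(s) dropped from the exact-distance set",
            call. = FALSE)
  }
  pool <- c(D1, D2[!is.na(D2)])
  if (length(pool) == 0) stop("estimation failure: empty distance pool", call. = FALSE)
  pool
}

#' Inclusion index: fraction of pooled distances inside the calibrated range
#'
#' @param pool numeric vector of pooled distances, mm.
#' @param profile a `calibration_profile`.
#' @return `P` in `[0, 1]`; the interval is closed, so boundary ties
#'   count as inside.
#' @export
inclusion_index <- function(pool, profile) {
  stopifnot(length(pool) >= 1)
  mean(pool >= profile$D_lower & pool <= profile$D_upper)
}

#' Fit a Gaussian peak to the P-vs-R curve
#'
#' Nonlinear least squares of `P(R) ~ A * exp(-(R - mu)^2 / (2 sigma^2))`,
#' initialized at the curve's argmax with the half-maximum width.  With
#' `offset = TRUE` a constant baseline term is added.  On non-convergence
#' the initializer (grid argmax) is returned with a warning.
#'
#' @param p_curve data frame with columns `R_t` and `P` (>= 5 rows,
#'   `max(P) > 0`).
#' @param offset add a constant baseline term; default `FALSE` (the
#'   P curve decays to zero away from the true radius).
#' @return list with `mean`, `sd`, `amplitude`, `converged`.
#' @export
fit_gaussian_peak <- function(p_curve, offset = FALSE) {
  stopifnot(nrow(p_curve) >= 5)
  R <- p_curve$R_t; P <- p_curve$P
  if (max(P) <= 0 || max(P) == min(P)) {
    stop("no-peak error: flat P curve", call. = FALSE)
  }
  imax <- which(P == max(P))
  if (length(imax) > 1 && any(diff(imax) > 1)) {
    warning("multiple equal peaks; converging to the initializer's basin",
            call. = FALSE)
  }
  # a contiguous plateau at the maximum is typical of the step-like P
  # curve; initialize at its center
  A0 <- max(P); mu0 <- mean(R[imax[c(1, length(imax))]])
  above <- R[P > A0 / 2]
  step <- if (length(R) > 1) min(diff(sort(R))) else 1
  sd0 <- max((max(above) - min(above)) / 2, step)
  df <- data.frame(R = R, P = P)
  fit <- if (offset) {
    try(minpack.lm::nlsLM(
      P ~ A * exp(-(R - mu)^2 / (2 * sigma^2)) + c0, data = df,
      start = list(A = A0, mu = mu0, sigma = sd0, c0 = min(P)),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  } else {
    try(minpack.lm::nlsLM(
      P ~ A * exp(-(R - mu)^2 / (2 * sigma^2)), data = df,
      start = list(A = A0, mu = mu0, sigma = sd0),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    warning("Gaussian fit did not converge; falling back to the grid argmax",
            call. = FALSE)
    return(list(mean = mu0, sd = sd0, amplitude = A0, converged = FALSE))
  }
  cf <- stats::coef(fit)
  list(mean = unname(cf["mu"]), sd = abs(unname(cf["sigma"])),
       amplitude = unname(cf["A"]), converged = TRUE)
}

#' Estimate the radius of an unknown plate from an ellipse sequence
#'
#' For every candidate radius on the line table's grid, pools the
#' line-model and exact distances, scores the fraction falling inside the
#' calibrated range (inclusion index P), fits a Gaussian to the P-vs-R
#' curve, and reports the fitted mean (clamped to the grid extent) as the
#' estimated radius.
#'
#' The exact distances are computed once at unit radius and scaled --
#' [distance_from_ellipse()] is exactly homogeneous in the candidate
#' radius -- so the per-candidate pools are identical to calling
#' [pooled_distances()] on each grid radius.
#'
#' @param obs data frame of metric observations.
#' @param cam a [camera_intrinsics()].
#' @param profile a `calibration_profile` built with the same camera.
#' @param table a `line_table` (see [build_line_table()]).
#' @param filter apply [filter_outliers()] first; default `TRUE`.
#' @param tilt_band_deg passed to [distance_from_ellipse()].
#' @param gaussian_offset passed to [fit_gaussian_peak()].
#' @param ... further arguments to [filter_outliers()].
#' @return object of class `radius_estimate` with `estimated_radius`,
#'   `gaussian_mean`, `gaussian_sd`, `gaussian_amplitude`, `p_curve`
#'   (data frame `R_t`, `P`), `n_frames_used`, `n_outliers_removed`.
#' @export
estimate_radius <- function(obs, cam, profile, table, filter = TRUE,
                            tilt_band_deg = c(10, 80),
                            gaussian_offset = FALSE, ...) {
  stopifnot(inherits(profile, "calibration_profile"), inherits(table, "line_table"))
  n_removed <- 0L
  if (filter && nrow(obs) >= 3) {
    fo <- filter_outliers(obs, ...)
    obs <- fo$kept
    n_removed <- length(fo$removed)
  }
  if (nrow(obs) == 0) stop("estimation failure: empty sequence", call. = FALSE)
  # unit-radius exact distances, scaled per candidate by homogeneity
  base <- rep(NA_real_, nrow(obs))
  for (i in seq_len(nrow(obs))) {
    sol <- try(distance_from_ellipse(obs_row(obs, i), cam, 1, tilt_band_deg),
               silent = TRUE)
    if (!inherits(sol, "try-error")) base[i] <- sol$distance_D
  }
  if (anyNA(base)) {
    warning(sum(is.na(base)), " frame(s) dropped from the exact-distance set",
            call. = FALSE)
  }
  base <- base[!is.na(base)]
  lines <- table$lines
  P <- vapply(seq_len(nrow(lines)), function(t) {
    pool <- c(lines$m[t] / obs$a + lines$n[t], lines$R_t[t] * base)
    inclusion_index(pool, profile)
  }, numeric(1))
  if (all(P == 0)) {
    stop("out-of-calibration-range error: no candidate radius maps the sequence into [D_lower, D_upper]",
         call. = FALSE)
  }
  p_curve <- data.frame(R_t = lines$R_t, P = P)
  g <- fit_gaussian_peak(p_curve, offset = gaussian_offset)
  grid_min <- min(lines$R_t); grid_max <- max(lines$R_t)
  est <- min(max(g$mean, grid_min), grid_max)
  if (est != g$mean) {
    warning("estimated radius clamped to the table grid extent", call. = FALSE)
  }
  structure(list(estimated_radius = est, gaussian_mean = g$mean,
                 gaussian_sd = g$sd, gaussian_amplitude = g$amplitude,
                 p_curve = p_curve,
                 n_frames_used = nrow(obs),
                 n_outliers_removed = n_removed),
            class = "radius_estimate")
}

#' @export
print.radius_estimate <- function(x, ...) {
  cat(sprintf("Estimated plate radius: %.1f mm (Gaussian mean %.2f, sd %.2f, amplitude %.3f)\n",
              x$estimated_radius, x$gaussian_mean, x$gaussian_sd,
              x$gaussian_amplitude))
  cat(sprintf("  %d frames used, %d outliers removed\n",
              x$n_frames_used, x$n_outliers_removed))
  invisible(x)
}

#' Plot the inclusion-index curve of a radius estimate
#'
#' @param x a `radius_estimate`.
#' @param ... passed to [plot()].
#' @export
plot.radius_estimate <- function(x, ...) {
  plot(x$p_curve$R_t, x$p_curve$P, xlab = "candidate radius R (mm)",
       ylab = "inclusion index P", pch = 16, cex = 0.6, ...)
  rr <- seq(min(x$p_curve$R_t), max(x$p_curve$R_t), length.out = 400)
  graphics::lines(rr, x$gaussian_amplitude *
                    exp(-(rr - x$gaussian_mean)^2 / (2 * x$gaussian_sd^2)),
                  col = "red3")
  graphics::abline(v = x$estimated_radius, lty = 2, col = "grey40")
  invisible(x)
}
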