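# Shared fixtures: a wide-angle chest-camera model and small oracles
# implemented independently of the package internals.

test_cam <- function() {
  camera_intrinsics(focal_length_mm = 3, pixel_pitch_mm = 0.003,
                    principal_point_px = c(640, 480),
                    image_size_px = c(1280, 960))
}

# random plate pose within the operating envelope; off-axis poses
# exercise the full cone-inversion path
random_pose <- function(off_axis_deg = 10) {
  R <- runif(1, 30, 165)
  D <- runif(1, 250, 800)
  g <- runif(1, 20, 70) * pi / 180
  ang <- runif(1, 0, off_axis_deg) * pi / 180
  az <- runif(1, 0, 2 * pi)
  ctr <- D * c(sin(ang) * cos(az), sin(ang) * sin(az), cos(ang))
  list(pose = circle_pose(ctr, c(0, cos(g), sin(g)), R), R = R, D = D,
       gamma = g)
}

# Independent brute-force implementation of the sparse-extreme-bin
# histogram trimming rule, using cut() rather than arithmetic binning.
brute_trim <- function(d, bins = 10) {
  breaks <- seq(min(d), max(d), length.out = bins + 1)
  idx <- as.integer(cut(d, breaks, right = FALSE, include.lowest = TRUE))
  idx[d == max(d)] <- bins
  counts <- tabulate(idx, nbins = bins)
  avg <- length(d) / bins
  keep <- rep(TRUE, length(d))
  if (counts[1] < avg / 2) keep[idx == 1] <- FALSE
  if (counts[bins] < avg / 2) keep[idx == bins] <- FALSE
  range(d[keep])
}

# Unconstrained algebraic conic fit (smallest right singular vector of
# the design matrix): the independent oracle for ellipse fitting.
svd_conic_fit <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(x^2, x * y, y^2, x, y, 1)
  v <- svd(A)$v[, 6]
  Q <- matrix(c(v[1], v[2] / 2, v[4] / 2,
                v[2] / 2, v[3], v[5] / 2,
                v[4] / 2, v[5] / 2, v[6]), 3, 3)
  conic_to_geometric(platescale:::normalize_conic(Q))
}

expect_ellipse_equal <- function(fit, e, tol = 1e-8) {
  expect_equal(fit$cx, e$cx, tolerance = tol)
  expect_equal(fit$cy, e$cy, tolerance = tol)
  expect_equal(fit$a, e$a, tolerance = tol)
  expect_equal(fit$b, e$b, tolerance = tol)
  expect_lt(platescale:::fold_angle_diff(fit$theta - e$theta), max(tol, 1e-8))
}
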