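# Direct least-squares ellipse fitting from boundary points, following
# the numerically stable partitioned formulation of the
# ellipse-constrained algebraic fit (the constraint 4*A*C - B^2 = 1 is
# built into the eigenproblem, so a hyperbola can never be returned).
# Points are centered and scaled before fitting for conditioning, which
# also makes the fit equivariant under translation and rotation.

#' Fit an ellipse to boundary points
#'
#' Ellipse-constrained direct least-squares conic fit.  Exact for points
#' lying exactly on an ellipse (five points determine the conic); with
#' noisy points it minimizes algebraic distance subject to the ellipse
#' constraint.  This is the fitting step used on manually selected plate
#' boundary points.
#'
#' @param points two-column matrix or data frame of (x, y) in image-plane
#'   mm; at least 5 points, not all collinear.
#' @param frame frame index attached to the result.
#' @return an [ellipse_obs()].
#' @examples
#' e <- ellipse_obs(1, -2, 3, 1.5, pi / 6)
#' pts <- sample_boundary_points(e, 6)
#' fit_ellipse_points(pts)
#' @export
fit_ellipse_points <- function(points, frame = 0L) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("points must have two columns", call. = FALSE)
  if (nrow(pts) < 5) stop("insufficient points: at least 5 required", call. = FALSE)
  ctr <- colMeans(pts)
  xc <- pts[, 1] - ctr[1]; yc <- pts[, 2] - ctr[2]
  s <- sqrt(mean(xc^2 + yc^2) / 2)
  if (s <= 0) stop("not_an_ellipse: degenerate point set", call. = FALSE)
  x <- xc / s; y <- yc / s

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12) {
    stop("not_an_ellipse: collinear or degenerate points", call. = FALSE)
  }
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  # apply the inverse of the constraint matrix for 4AC - B^2 = 1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0 & abs(Im(ev$values)) < 1e-8)
  if (length(ok) == 0) stop("not_an_ellipse: no ellipse satisfies the constraint",
                            call. = FALSE)
  a1 <- vecs[, ok[1]]
  a2 <- drop(Tm %*% a1)
  co <- c(a1, a2)  # A, B, C, D, E, F in normalized coordinates

  Qn <- matrix(c(co[1], co[2] / 2, co[4] / 2,
                 co[2] / 2, co[3], co[5] / 2,
                 co[4] / 2, co[5] / 2, co[6]), 3, 3)
  # undo the normalization p_norm = (p - ctr) / s
  Tr <- matrix(c(1 / s, 0, -ctr[1] / s,
                 0, 1 / s, -ctr[2] / s,
                 0, 0, 1), 3, 3, byrow = TRUE)
  Q <- t(Tr) %*% Qn %*% Tr
  conic_to_geometric(normalize_conic((Q + t(Q)) / 2), frame = frame)
}

#' Convenience wrapper: fit an ellipse to pixel-space points
#'
#' Converts pixel coordinates to image-plane mm with the camera
#' intrinsics, then calls [fit_ellipse_points()].
#'
#' @param points_px two-column matrix of (x, y) in pixels.
#' @param cam a [camera_intrinsics()].
#' @param frame frame index.
#' @return an [ellipse_obs()] in image-plane mm.
#' @export
fit_ellipse_points_px <- function(points_px, cam, frame = 0L) {
  pts <- as.matrix(points_px)
  mm <- cbind((pts[, 1] - cam$principal_point_px[1]) * cam$pixel_pitch_mm,
              (pts[, 2] - cam$principal_point_px[2]) * cam$pixel_pitch_mm)
  fit_ellipse_points(mm, frame = frame)
}

#' Sample points on an ellipse boundary
#'
#' Fixture generator: `n` points at uniformly spaced parametric angles
#' within `arc`, optionally displaced by isotropic Gaussian noise.  A
#' partial arc emulates a plate rim partly occluded by food or shadow.
#'
#' @param e an [ellipse_obs()].
#' @param n number of points.
#' @param arc parametric angle interval in radians; default the full
#'   boundary.
#' @param noise_sd isotropic Gaussian displacement sd, mm; default 0.
#' @param seed integer seed or `NULL`.
#' @return `n` x 2 matrix of (x, y) in mm.
#' @export
sample_boundary_points <- function(e, n, arc = c(0, 2 * pi), noise_sd = 0,
                                   seed = NULL) {
  stopifnot(inherits(e, "ellipse_obs"), n >= 1, length(arc) == 2, arc[2] > arc[1])
  full <- (arc[2] - arc[1]) >= 2 * pi - 1e-12
  phi <- if (full) seq(arc[1], arc[2], length.out = n + 1)[seq_len(n)]
         else seq(arc[1], arc[2], length.out = n)
  ct <- cos(e$theta); st <- sin(e$theta)
  px <- e$cx + e$a * cos(phi) * ct - e$b * sin(phi) * st
  py <- e$cy + e$a * cos(phi) * st + e$b * sin(phi) * ct
  with_seed(seed, {
    if (noise_sd > 0) {
      px <- px + stats::rnorm(n, 0, noise_sd)
      py <- py + stats::rnorm(n, 0, noise_sd)
    }
    cbind(x = px, y = py)
  })
}
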