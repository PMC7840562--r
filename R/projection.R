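# Exact perspective geometry of a circle: forward projection to an image
# ellipse, and inversion of an image ellipse to camera-to-plate distance
# for a candidate plate radius via cone-plane intersection.
#
# Camera frame: right-handed, origin at the optical center, z along the
# optical axis into the scene, x right, y down (matching image-plane
# coordinates).  All lengths in mm.

#' Pose of a 3D circle in the camera frame
#'
#' @param center numeric length-3 center of the circle (mm), z forward.
#' @param normal numeric length-3 normal of the supporting plane
#'   (normalized internally).
#' @param radius circle radius in mm.
#' @return object of class `circle_pose`.
#' @export
circle_pose <- function(center, normal, radius) {
  stopifnot(length(center) == 3, length(normal) == 3, length(radius) == 1)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (center[3] <= 0) stop("circle center must be in front of the camera (z > 0)",
                           call. = FALSE)
  structure(list(center = as.numeric(center), normal = unit3(as.numeric(normal)),
                 radius = as.numeric(radius)),
            class = "circle_pose")
}

#' @export
print.circle_pose <- function(x, ...) {
  cat(sprintf("Circle pose: center (%.4g, %.4g, %.4g) mm, normal (%.3f, %.3f, %.3f), R = %.4g mm\n",
              x$center[1], x$center[2], x$center[3],
              x$normal[1], x$normal[2], x$normal[3], x$radius))
  invisible(x)
}

# Orthonormal in-plane basis (u, v) completing `n` to a right-handed frame.
plane_basis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit3(cross3(n, ref))
  v <- cross3(n, u)
  list(u = u, v = v)
}

#' Perspective projection of a 3D circle to its image ellipse
#'
#' Computes the exact pinhole image of a circle in closed form through the
#' homography mapping the circle's supporting plane to the image plane
#' (equivalently, via the quadric of the circle's back-projection cone) --
#' no point sampling is involved.
#'
#' @param pose a [circle_pose()] with every circle point in front of the
#'   camera.
#' @param cam a [camera_intrinsics()].
#' @param frame frame index attached to the returned observation.
#' @return an [ellipse_obs()] in image-plane mm.
#' @examples
#' cam <- camera_intrinsics(3, 0.003, c(640, 480), c(1280, 960))
#' # fronto-parallel plate: image is a circle of radius f*R/D
#' project_circle(circle_pose(c(0, 0, 400), c(0, 0, 1), 100), cam)
#' @export
project_circle <- function(pose, cam, frame = 0L) {
  stopifnot(inherits(pose, "circle_pose"), inherits(cam, "camera_intrinsics"))
  n <- pose$normal; c0 <- pose$center; R <- pose$radius
  if (abs(sum(n * c0)) < 1e-9 * sqrt(sum(c0^2))) {
    stop("degenerate projection: circle plane passes through the optical center",
         call. = FALSE)
  }
  b <- plane_basis(n)
  zmin <- c0[3] - R * sqrt(b$u[3]^2 + b$v[3]^2)
  if (zmin <= 0) {
    stop("circle not entirely in front of the camera", call. = FALSE)
  }
  # plane coords (s, t, 1) -> 3D point; circle there is s^2 + t^2 = R^2
  H <- cbind(b$u, b$v, c0)
  G <- diag(c(cam$focal_length_mm, cam$focal_length_mm, 1)) %*% H
  Gi <- solve(G)
  Q <- t(Gi) %*% diag(c(1, 1, -R^2)) %*% Gi
  Q <- (Q + t(Q)) / 2
  conic_to_geometric(normalize_conic(Q), frame = frame)
}

# Intersect the cone t(x) %*% M %*% x = 0 with the plane {x : n . x = 1}.
# Returns the section's center (3D), its geometric parameters in the
# plane, and an is-circle flag.  The cone is symmetric about the origin,
# so the section at n . x = -1 is the point-mirrored copy.
cone_plane_section <- function(M, n) {
  b <- plane_basis(n)
  W <- cbind(b$u, b$v, n)
  B <- t(W) %*% M %*% W
  B <- (B + t(B)) / 2
  geo <- conic_to_geometric(B)
  ctr <- n + geo$cx * b$u + geo$cy * b$v
  list(center = ctr, radius = (geo$a + geo$b) / 2,
       circularity = geo$b / geo$a)
}

#' Camera-to-plate distance from a single image ellipse
#'
#' Inverts the perspective projection of a circle: the image ellipse is
#' back-projected through the optical center into an elliptic cone; the
#' (up to two) plane orientations cutting that cone in a circle are found
#' from its eigen-decomposition, each solution is scaled so the circle
#' radius equals the candidate plate radius `R`, and the camera-to-plate
#' distance is the norm of the recovered circle center.  The two circular
#' sections are mirror images under a symmetry plane of the cone, so they
#' yield the same distance; they differ in plane orientation, and the
#' returned pose is the solution whose implied tilt falls inside
#' `tilt_band_deg` (preferring the smaller reprojection residual when both
#' qualify).
#'
#' Distance is exactly homogeneous in the candidate radius: doubling `R`
#' doubles the returned distance.
#'
#' @param e an [ellipse_obs()] in image-plane mm.
#' @param cam a [camera_intrinsics()].
#' @param R candidate plate radius in mm.
#' @param tilt_band_deg admissible band for the tilt angle between the
#'   optical axis and the plate plane, in degrees.  A chest-worn camera
#'   looking down at a table constrains this; default `c(10, 80)`.
#' @return object of class `distance_solution` with elements
#'   `distance_D` (mm), `pose` (a [circle_pose()]), `candidate_radius`,
#'   and `ambiguity_count` (1 or 2 geometrically admissible cuts).
#' @export
distance_from_ellipse <- function(e, cam, R, tilt_band_deg = c(10, 80)) {
  stopifnot(inherits(e, "ellipse_obs"), inherits(cam, "camera_intrinsics"))
  if (!is.finite(R) || R <= 0) stop("candidate radius must be positive", call. = FALSE)
  f <- cam$focal_length_mm
  Q <- geometric_to_conic(e)
  K <- diag(c(f, f, 1))
  M <- K %*% Q %*% K
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  lam <- ee$values; V <- ee$vectors
  if (sum(lam > 0) == 1) lam <- -lam      # make signature (+,+,-)
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]; V <- V[, ord]
  if (!(lam[2] > 0 && lam[3] < 0)) {
    stop("estimation error: back-projected cone is degenerate", call. = FALSE)
  }

  # circular cone: plate seen frontally; one-parameter family of cuts.
  if (lam[1] - lam[2] <= 1e-9 * abs(lam[1])) {
    D <- f * R / e$a
    dir <- unit3(c(e$cx / f, e$cy / f, 1))
    pose <- circle_pose(D * dir, -dir, R)
    return(structure(list(distance_D = D, pose = pose, candidate_radius = R,
                          ambiguity_count = 1L),
                     class = "distance_solution"))
  }

  al <- sqrt((lam[1] - lam[2]) / (lam[1] - lam[3]))
  be <- sqrt((lam[2] - lam[3]) / (lam[1] - lam[3]))
  cands <- list()
  for (sgn in c(1, -1)) {
    n <- al * V[, 1] + sgn * be * V[, 3]
    sec <- try(cone_plane_section(M, n), silent = TRUE)
    if (inherits(sec, "try-error")) next
    ctr <- sec$center
    if (ctr[3] < 0) ctr <- -ctr           # use the nappe in front of the camera
    if (ctr[3] <= 0) next
    k <- R / sec$radius
    center <- k * ctr
    # orient the plate normal toward the camera
    n_out <- if (sum(n * center) > 0) -n else n
    tilt <- asin(min(1, abs(n_out[3])))   # angle between optical axis and plane
    cands[[length(cands) + 1]] <- list(
      center = center, normal = n_out, tilt = tilt,
      circularity = sec$circularity)
  }
  if (length(cands) == 0) {
    stop("estimation error: no admissible circular section of the back-projected cone",
         call. = FALSE)
  }
  band <- deg2rad(tilt_band_deg)
  in_band <- vapply(cands, function(s) s$tilt >= band[1] && s$tilt <= band[2],
                    logical(1))
  pool <- if (any(in_band)) cands[in_band] else cands
  if (length(pool) > 1) {
    # tie-break on reprojection residual against the observed ellipse
    resid <- vapply(pool, function(s) {
      pe <- try(project_circle(circle_pose(s$center, s$normal, R), cam),
                silent = TRUE)
      if (inherits(pe, "try-error")) return(Inf)
      sum((c(pe$cx, pe$cy, pe$a, pe$b) - c(e$cx, e$cy, e$a, e$b))^2)
    }, numeric(1))
    pool <- pool[which.min(resid)]
  }
  sel <- pool[[1]]
  pose <- circle_pose(sel$center, sel$normal, R)
  structure(list(distance_D = sqrt(sum(sel$center^2)), pose = pose,
                 candidate_radius = R,
                 ambiguity_count = length(cands)),
            class = "distance_solution")
}

#' @export
print.distance_solution <- function(x, ...) {
  cat(sprintf("Distance solution: D = %.4g mm for candidate R = %.4g mm (%d admissible cut%s)\n",
              x$distance_D, x$candidate_radius, x$ambiguity_count,
              if (x$ambiguity_count == 1) "" else "s"))
  invisible(x)
}
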