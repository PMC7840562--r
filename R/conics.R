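# Conversions between geometric ellipse parameters and the symmetric 3x3
# conic coefficient matrix in homogeneous image-plane coordinates (mm).
# Points p = (x, y, 1) on the ellipse satisfy  t(p) %*% Q %*% p = 0.

# Scale convention: Q[3,3] == -1 whenever the bottom-right entry is
# nonzero (the origin not on the conic); otherwise unit Frobenius norm.
normalize_conic <- function(Q) {
  frob <- sqrt(sum(Q^2))
  if (frob == 0) stop("zero conic matrix", call. = FALSE)
  if (abs(Q[3, 3]) > 1e-12 * frob) {
    -Q / Q[3, 3]
  } else {
    Q / frob
  }
}

#' Conic matrix of an ellipse
#'
#' Builds the homogeneous quadratic form whose zero set is the given
#' ellipse.  This is the algebraic representation used by the projection
#' and pose-recovery code.
#'
#' @param e an [ellipse_obs()].
#' @return symmetric 3x3 matrix `Q` with `t(p) %*% Q %*% p == 0` for
#'   homogeneous points `p` on the ellipse, normalized so `Q[3,3] == -1`
#'   when that entry is nonzero.
#' @seealso [conic_to_geometric()]
#' @export
geometric_to_conic <- function(e) {
  stopifnot(inherits(e, "ellipse_obs"))
  ct <- cos(e$theta); st <- sin(e$theta)
  ia2 <- 1 / e$a^2; ib2 <- 1 / e$b^2
  A <- ct^2 * ia2 + st^2 * ib2
  B2 <- ct * st * (ia2 - ib2)
  C <- st^2 * ia2 + ct^2 * ib2
  M2 <- matrix(c(A, B2, B2, C), 2, 2)
  c0 <- c(e$cx, e$cy)
  d <- -drop(M2 %*% c0)
  Q <- rbind(cbind(M2, d), c(d, drop(t(c0) %*% M2 %*% c0) - 1))
  dimnames(Q) <- NULL
  normalize_conic(Q)
}

#' Geometric ellipse parameters of a conic matrix
#'
#' Inverse of [geometric_to_conic()].  Fails with a `not_an_ellipse`
#' error for hyperbolas, parabolas, degenerate conics and imaginary
#' ellipses.
#'
#' @param Q symmetric 3x3 conic matrix.
#' @param frame frame index attached to the result.
#' @return an [ellipse_obs()].
#' @export
conic_to_geometric <- function(Q, frame = 0L) {
  stopifnot(is.matrix(Q), all(dim(Q) == c(3, 3)))
  if (max(abs(Q - t(Q))) > 1e-8 * max(abs(Q))) {
    stop("conic matrix must be symmetric", call. = FALSE)
  }
  M2 <- Q[1:2, 1:2]
  det2 <- M2[1, 1] * M2[2, 2] - M2[1, 2]^2
  if (det2 <= 1e-14 * sum(M2^2)) {
    stop("not_an_ellipse: conic is not an ellipse (non-positive definite quadratic part)",
         call. = FALSE)
  }
  d <- Q[1:2, 3]
  c0 <- drop(solve(M2, -d))
  # value of the form at its center; ellipse equation becomes
  # t(p - c0) %*% M2 %*% (p - c0) + s = 0
  s <- Q[3, 3] - drop(t(d) %*% solve(M2, d))
  ev <- eigen(M2, symmetric = TRUE)
  mu <- ev$values; V <- ev$vectors
  if (mu[1] < 0) {          # both eigenvalues negative: flip overall sign
    mu <- -rev(mu); V <- V[, 2:1]; s <- -s
  }
  if (s >= 0) {
    stop("not_an_ellipse: conic has no real points (imaginary ellipse)",
         call. = FALSE)
  }
  a <- sqrt(-s / mu[2])     # mu[2] = smaller eigenvalue -> major axis
  b <- sqrt(-s / mu[1])
  if (abs(mu[1] - mu[2]) <= 1e-12 * abs(mu[1])) {
    th <- 0                  # circle: orientation is arbitrary
  } else {
    v <- V[, 2]
    th <- atan2(v[2], v[1])
  }
  ellipse_obs(c0[1], c0[2], a, b, th, frame)
}
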