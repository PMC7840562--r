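# Internal helpers shared across modules.

cross3 <- function(x, y) {
  c(x[2] * y[3] - x[3] * y[2],
    x[3] * y[1] - x[1] * y[3],
    x[1] * y[2] - x[2] * y[1])
}

unit3 <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot normalize a zero vector", call. = FALSE)
  x / nrm
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalize an ellipse orientation angle to [0, pi)
#'
#' Ellipses are invariant under a half-turn of the major axis, so
#' orientations are stored modulo pi.
#'
#' @param theta angle in radians.
#' @return angle in `[0, pi)`.
#' @keywords internal
normalize_theta <- function(theta) {
  th <- theta %% pi
  # guard against pi itself surviving the modulo through rounding
  th[th >= pi] <- 0
  th
}

# Smallest angular difference between two major-axis orientations,
# folded to [0, pi/2] (an ellipse's axis is a line, not a direction).
fold_angle_diff <- function(dtheta) {
  d <- abs(dtheta) %% pi
  pmin(d, pi - d)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.  seed = NULL leaves the
# stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation that stays inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483629 * 7919 + k * 104729) %% 2147483629)
}
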