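# Cross-estimation experiment and error metrics: each plate serves in
# turn as the calibration reference and every other plate's radius is
# estimated, yielding M*(M-1) estimates summarized by signed, absolute
# and root-mean-square percentage errors.

#' Signed percentage error of a radius estimate
#'
#' @param R_est estimated radius, mm (vectorized).
#' @param R_true true radius, mm (> 0).
#' @return `(R_est - R_true) / R_true` as a fraction.
#' @export
percentage_error <- function(R_est, R_true) {
  if (any(R_true <= 0)) stop("invalid input: true radius must be positive",
                             call. = FALSE)
  (R_est - R_true) / R_true
}

# package-level cache of line tables keyed by their configuration
.table_cache <- new.env(parent = emptyenv())

cached_line_table <- function(f, radius_grid, gamma_band_deg, distance_band_mm,
                              n_pairs, seed) {
  key <- paste(signif(c(f, radius_grid, gamma_band_deg, distance_band_mm), 12),
               n_pairs, seed, collapse = "|")
  if (!is.null(.table_cache[[key]])) return(.table_cache[[key]])
  tab <- build_line_table(f, radius_grid, gamma_band_deg, distance_band_mm,
                          n_pairs, seed)
  .table_cache[[key]] <- tab
  tab
}

#' Leave-one-plate-as-reference cross-estimation
#'
#' For every episode `k` of a study: calibrate on that episode with its
#' true radius, build (or reuse from cache) a line table over the
#' profile-derived distance band, and estimate the radius of every other
#' episode `j != k`.  The diagonal of the returned matrix holds the true
#' radii; a failed estimation leaves its cell `NA` with a warning rather
#' than aborting.
#'
#' @param study a `study` from [generate_study()], or any list with
#'   elements `episodes` (each holding `observations` and
#'   `ground_truth$true_radius`) and `radii`.
#' @param cam a [camera_intrinsics()].
#' @param bins histogram bins for calibration; default 10.
#' @param radius_grid,gamma_band_deg,n_pairs line-table settings (the
#'   distance band is derived from each reference's profile).
#' @param table_seed seed for the simulated line tables.
#' @param ... further arguments to [estimate_radius()].
#' @return object of class `cross_estimates`: list with `estimates`
#'   (M x M matrix, true radii on the diagonal) and `true_radii`.
#' @export
cross_estimate_matrix <- function(study, cam, bins = 10,
                                  radius_grid = c(30, 165, 1),
                                  gamma_band_deg = c(20, 70),
                                  n_pairs = 2000, table_seed = 1L, ...) {
  eps <- study$episodes
  M <- length(eps)
  stopifnot(M >= 2)
  radii <- study$radii
  mat <- matrix(NA_real_, M, M,
                dimnames = list(paste0("ref", seq_len(M)),
                                paste0("plate", seq_len(M))))
  diag(mat) <- radii
  for (k in seq_len(M)) {
    prof <- calibrate(eps[[k]]$observations, cam, radii[k], bins = bins,
                      created_from = paste0("episode", k))
    tab <- cached_line_table(cam$focal_length_mm, radius_grid, gamma_band_deg,
                             table_band_for_profile(prof), n_pairs, table_seed)
    for (j in seq_len(M)[-k]) {
      est <- try(estimate_radius(eps[[j]]$observations, cam, prof, tab, ...),
                 silent = TRUE)
      if (inherits(est, "try-error")) {
        warning("estimation failed for reference ", k, ", plate ", j,
                call. = FALSE)
      } else {
        mat[k, j] <- est$estimated_radius
      }
    }
  }
  structure(list(estimates = mat, true_radii = radii),
            class = "cross_estimates")
}

#' Summarize cross-estimation errors
#'
#' Computes, over all filled off-diagonal cells, the mean signed
#' percentage error (mPE), mean absolute percentage error (maPE) and the
#' root mean square of the percentage errors (mrRMSE).  Missing cells are
#' excluded with the denominator adjusted and a warning.
#'
#' @param x a `cross_estimates` object, or a matrix of estimates paired
#'   with `true_radii`.
#' @param true_radii true radii (taken from `x` when it is a
#'   `cross_estimates`).
#' @return object of class `evaluation_report`: list with the three
#'   metrics as fractions, their `*_pct` percentage forms, `M`,
#'   `n_estimates` and the `estimates` matrix.
#' @export
summarize_errors <- function(x, true_radii = NULL) {
  if (inherits(x, "cross_estimates")) {
    mat <- x$estimates; true_radii <- x$true_radii
  } else {
    mat <- as.matrix(x)
  }
  M <- length(true_radii)
  stopifnot(all(dim(mat) == c(M, M)))
  pe <- c()
  for (k in seq_len(M)) for (j in seq_len(M)[-k]) {
    if (!is.na(mat[k, j])) pe <- c(pe, percentage_error(mat[k, j], true_radii[j]))
  }
  if (length(pe) < 1) stop("empty report: no filled estimates", call. = FALSE)
  if (length(pe) < M * (M - 1)) {
    warning(M * (M - 1) - length(pe), " missing cell(s) excluded from the metrics",
            call. = FALSE)
  }
  mPE <- mean(pe); maPE <- mean(abs(pe)); mrRMSE <- sqrt(mean(pe^2))
  structure(list(mPE = mPE, maPE = maPE, mrRMSE = mrRMSE,
                 mPE_pct = 100 * mPE, maPE_pct = 100 * maPE,
                 mrRMSE_pct = 100 * mrRMSE,
                 M = M, n_estimates = length(pe),
                 estimates = mat, true_radii = true_radii),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Cross-estimation report: M = %d plates, %d estimates\n",
              x$M, x$n_estimates))
  cat(sprintf("  mPE = %.2f%%   maPE = %.2f%%   mrRMSE = %.2f%%\n",
              x$mPE_pct, x$maPE_pct, x$mrRMSE_pct))
  invisible(x)
}
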