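# Ground-truthed synthetic eating episodes.  The generator emulates the
# quasiperiodic torso motion of a seated eater wearing a chest camera: the
# camera-to-plate distance oscillates as the person leans in to fetch
# food, the tilt angle drifts smoothly, and the plate's exact perspective
# image is perturbed by measurement noise and occasional non-eating
# outlier frames.

#' Configuration of a synthetic eating episode
#'
#' Defaults describe a realistic chest-camera meal: one image every 4-6 s
#' for about 60 frames, camera-to-plate distance oscillating around
#' 450 mm with a 120 mm lean-in amplitude and a roughly 12-frame
#' reach-fetch cycle, and plate-plane tilt drifting inside 20-70 degrees.
#'
#' @param true_radius plate radius, mm.
#' @param n_frames frames in the episode; default 60.
#' @param base_distance mean camera-to-plate distance, mm; default 450.
#' @param oscillation_amplitude sinusoidal lean-in amplitude, mm; default 120.
#' @param oscillation_period period of the lean cycle, frames; default 12.
#' @param distance_jitter_sd stationary sd of the AR(1) distance jitter,
#'   mm; default 15 (body motion is quasiperiodic, not periodic).
#' @param gamma_band_deg tilt band, degrees; default `c(20, 70)`.
#' @param gamma_smoothness AR(1) coefficient of the tilt (and jitter)
#'   process in `[0, 1)`; default 0.8.
#' @param ellipse_noise_fraction relative sd of the multiplicative noise
#'   on the semi-axes (and, scaled by `a`, additive noise on the ellipse
#'   center); default 0 (noise-free).
#' @param outlier_rate probability that a frame is replaced by a
#'   non-eating outlier (teleported center, random orientation); default 0.
#' @param off_axis_deg maximal angular offset of the plate center from
#'   the optical axis; 0 (default) keeps the exact simplified geometry,
#'   positive values stress the full cone-inversion path.
#' @param seed integer seed.
#' @return object of class `episode_config`.
#' @export
episode_config <- function(true_radius, n_frames = 60, base_distance = 450,
                           oscillation_amplitude = 120, oscillation_period = 12,
                           distance_jitter_sd = 15, gamma_band_deg = c(20, 70),
                           gamma_smoothness = 0.8, ellipse_noise_fraction = 0,
                           outlier_rate = 0, off_axis_deg = 0, seed = 1L) {
  stopifnot(true_radius > 0, n_frames >= 1, oscillation_period > 0)
  if (base_distance - oscillation_amplitude <= true_radius) {
    stop("configuration error: base_distance - oscillation_amplitude must exceed true_radius",
         call. = FALSE)
  }
  for (v in c(gamma_smoothness, ellipse_noise_fraction, outlier_rate)) {
    if (v < 0 || v >= 1) {
      stop("configuration error: rates and fractions must lie in [0, 1)", call. = FALSE)
    }
  }
  structure(as.list(environment())[c(
    "true_radius", "n_frames", "base_distance", "oscillation_amplitude",
    "oscillation_period", "distance_jitter_sd", "gamma_band_deg",
    "gamma_smoothness", "ellipse_noise_fraction", "outlier_rate",
    "off_axis_deg", "seed")], class = "episode_config")
}

# stationary AR(1) process of length n with mean 0 and stationary sd `sd`
ar1_series <- function(n, phi, sd) {
  if (sd <= 0) return(rep(0, n))
  e <- stats::rnorm(n, 0, sd)
  x <- numeric(n)
  x[1] <- e[1]
  if (n > 1) for (t in 2:n) x[t] <- phi * x[t - 1] + sqrt(1 - phi^2) * e[t]
  x
}

#' Generate a distance/tilt trajectory for an episode
#'
#' Distance is a sinusoid plus AR(1) jitter; tilt is an AR(1) process
#' around the middle of the tilt band, clipped to the band.
#'
#' @param cfg an [episode_config()].
#' @return data frame with columns `frame`, `distance` (mm), `gamma` (rad).
#' @export
generate_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "episode_config"))
  with_seed(cfg$seed, {
    t <- seq_len(cfg$n_frames)
    dist <- cfg$base_distance +
      cfg$oscillation_amplitude * sin(2 * pi * t / cfg$oscillation_period) +
      ar1_series(cfg$n_frames, cfg$gamma_smoothness, cfg$distance_jitter_sd)
    dist <- pmax(dist, 1.05 * cfg$true_radius)  # camera never inside the plate
    band <- deg2rad(cfg$gamma_band_deg)
    mid <- mean(band); half <- diff(band) / 2
    g <- mid + ar1_series(cfg$n_frames, cfg$gamma_smoothness, half / 2)
    g <- pmin(pmax(g, band[1]), band[2])
    data.frame(frame = t - 1L, distance = dist, gamma = g)
  })
}

#' Generate a synthetic eating episode with ground truth
#'
#' Per frame, a circle pose is constructed at the trajectory's distance
#' and tilt (optical axis through the plate center and camera level by
#' default; `off_axis_deg > 0` shifts the plate laterally), projected
#' exactly with [project_circle()], and perturbed: multiplicative noise
#' on the semi-axes, center noise proportional to the semimajor axis, and
#' outlier frames with a teleported center and random orientation.
#'
#' @param cfg an [episode_config()].
#' @param cam a [camera_intrinsics()].
#' @return object of class `episode`: list with `observations` (metric
#'   data frame), `pixels` (pixel CSV layout), `ground_truth` (per-frame
#'   `distance`, `gamma`, `outlier` flags, the `poses` list and
#'   `true_radius`), and `config`.
#' @export
generate_episode <- function(cfg, cam) {
  stopifnot(inherits(cfg, "episode_config"), inherits(cam, "camera_intrinsics"))
  traj <- generate_trajectory(cfg)
  with_seed(derive_seed(cfg$seed, 1L), {
    n <- cfg$n_frames
    half_w <- cam$image_size_px[1] / 2 * cam$pixel_pitch_mm
    half_h <- cam$image_size_px[2] / 2 * cam$pixel_pitch_mm
    poses <- vector("list", n)
    rows <- vector("list", n)
    outlier <- stats::runif(n) < cfg$outlier_rate
    for (i in seq_len(n)) {
      g <- traj$gamma[i]
      dir <- c(0, 0, 1)
      if (cfg$off_axis_deg > 0) {
        ang <- deg2rad(stats::runif(1, 0, cfg$off_axis_deg))
        az <- stats::runif(1, 0, 2 * pi)
        dir <- unit3(c(sin(ang) * cos(az), sin(ang) * sin(az), cos(ang)))
      }
      pose <- circle_pose(traj$distance[i] * dir, c(0, cos(g), sin(g)),
                          cfg$true_radius)
      poses[[i]] <- pose
      e <- project_circle(pose, cam, frame = i - 1L)
      a <- e$a; b <- e$b; cx <- e$cx; cy <- e$cy; th <- e$theta
      if (cfg$ellipse_noise_fraction > 0) {
        nf <- cfg$ellipse_noise_fraction
        a <- a * (1 + stats::rnorm(1, 0, nf))
        b <- b * (1 + stats::rnorm(1, 0, nf))
        b <- min(b, a)
        cx <- cx + stats::rnorm(1, 0, nf * e$a)
        cy <- cy + stats::rnorm(1, 0, nf * e$a)
      }
      if (outlier[i]) {
        cx <- stats::runif(1, -0.8 * half_w, 0.8 * half_w)
        cy <- stats::runif(1, -0.8 * half_h, 0.8 * half_h)
        th <- stats::runif(1, 0, pi)
      }
      rows[[i]] <- data.frame(frame = i - 1L, cx = cx, cy = cy, a = a, b = b,
                              theta = normalize_theta(th))
    }
    obs <- do.call(rbind, rows)
    structure(list(observations = obs,
                   pixels = image_plane_to_pixels(obs, cam),
                   ground_truth = list(distance = traj$distance,
                                       gamma = traj$gamma,
                                       outlier = outlier,
                                       poses = poses,
                                       true_radius = cfg$true_radius),
                   config = cfg),
              class = "episode")
  })
}

#' @export
print.episode <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("Synthetic episode: R = %g mm, %d frames, D in [%.0f, %.0f] mm, %d outlier frame(s)\n",
              gt$true_radius, nrow(x$observations), min(gt$distance),
              max(gt$distance), sum(gt$outlier)))
  invisible(x)
}

#' Generate a multi-plate study sharing one eating environment
#'
#' One episode per plate radius, all drawing distance and tilt
#' trajectories from the same environment template (the fixed-environment
#' premise of the method) with distinct derived sub-seeds.
#'
#' @param radii vector of true plate radii, mm (>= 2).
#' @param template an [episode_config()] whose `true_radius` is ignored.
#' @param cam a [camera_intrinsics()].
#' @param seed study-level integer seed.
#' @return object of class `study`: list of `episode`s plus `radii` and `seed`.
#' @export
generate_study <- function(radii, template, cam, seed = 1L) {
  stopifnot(length(radii) >= 2, inherits(template, "episode_config"))
  eps <- lapply(seq_along(radii), function(k) {
    cfg <- template
    cfg$true_radius <- radii[k]
    cfg$seed <- derive_seed(seed, 100 + k)
    if (cfg$base_distance - cfg$oscillation_amplitude <= cfg$true_radius) {
      stop("configuration error: template distances too close for radius ",
           radii[k], call. = FALSE)
    }
    generate_episode(cfg, cam)
  })
  structure(list(episodes = eps, radii = as.numeric(radii),
                 seed = as.integer(seed)),
            class = "study")
}
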