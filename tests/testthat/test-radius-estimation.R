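cam <- test_cam()

make_profile <- function(ep, R) calibrate(ep$observations, cam, R, bins = 10)

test_that("outlier filtering flags exactly the injected non-eating frames", {
  cfg <- episode_config(true_radius = 100, n_frames = 40, seed = 12)
  ep <- generate_episode(cfg, cam)
  clean <- filter_outliers(ep$observations)
  expect_length(clean$removed, 0)
  expect_equal(nrow(clean$kept), 40)

  # teleport three well-separated frames
  obs <- ep$observations
  for (i in c(8, 19, 31)) {
    obs$cx[i] <- obs$cx[i] + 1.2
    obs$cy[i] <- obs$cy[i] - 0.9
    obs$theta[i] <- platescale:::normalize_theta(obs$theta[i] + 1.2)
  }
  out <- filter_outliers(obs)
  expect_equal(out$removed, c(8, 19, 31))

  # identical frames: MAD = 0 is guarded by the absolute floors
  const <- do.call(rbind, replicate(6, obs[1, ], simplify = FALSE))
  const$frame <- 0:5
  expect_length(filter_outliers(const)$removed, 0)
})

test_that("pooling doubles the data and respects radius homogeneity", {
  cfg <- episode_config(true_radius = 100, n_frames = 10, seed = 14)
  ep <- generate_episode(cfg, cam)
  tab <- build_line_table(cam$focal_length_mm, n_pairs = 500, seed = 2)
  line <- platescale:::table_line(tab, 100)
  pool <- pooled_distances(ep$observations, cam, line, 100)
  expect_length(pool, 20)

  # exact distances double with the candidate radius; line predictions
  # follow through the radius-scaled line model
  pool2 <- pooled_distances(ep$observations, cam, line, 200)
  expect_equal(pool2[11:20], 2 * pool[11:20], tolerance = 1e-12)

  # fronto-parallel frames: the two distance sets nearly coincide
  D <- c(380, 420, 470)
  fr <- data.frame(frame = 0:2, cx = 0, cy = 0, a = 3 * 100 / D,
                   b = 3 * 100 / D, theta = 0)
  pf <- pooled_distances(fr, cam, line, 100)
  expect_lt(max(abs(pf[1:3] - pf[4:6]) / pf[4:6]), 0.05)
})

test_that("inclusion index counts closed-interval membership", {
  prof <- structure(list(D_lower = 150, D_upper = 350),
                    class = "calibration_profile")
  expect_equal(inclusion_index(c(200, 300), prof), 1)
  expect_equal(inclusion_index(c(10, 500), prof), 0)
  expect_equal(inclusion_index(c(100, 200, 300, 400), prof), 0.5)
  expect_equal(inclusion_index(c(150, 350), prof), 1)  # boundaries inside
})

test_that("Gaussian peak fitting recovers parameters and handles edge cases", {
  R <- seq(30, 165, 1)
  P <- 0.8 * exp(-(R - 120)^2 / (2 * 15^2))
  g <- fit_gaussian_peak(data.frame(R_t = R, P = P))
  expect_equal(g$mean, 120, tolerance = 1e-6)
  expect_equal(g$sd, 15, tolerance = 1e-6)
  expect_equal(g$amplitude, 0.8, tolerance = 1e-6)

  # symmetric triangular peak: the mean lands on the apex
  Pt <- pmax(0, 1 - abs(R - 100) / 30)
  gt <- fit_gaussian_peak(data.frame(R_t = R, P = Pt))
  expect_lt(abs(gt$mean - 100), 1)

  expect_error(fit_gaussian_peak(data.frame(R_t = R, P = rep(0.4, length(R)))),
               "no-peak")
  # two separated equal peaks: documented initializer-basin behavior
  P2 <- exp(-(R - 60)^2 / 50) + exp(-(R - 140)^2 / 50)
  P2 <- P2 / max(P2)
  expect_warning(fit_gaussian_peak(data.frame(R_t = R, P = P2)),
                 "multiple equal peaks")
})

test_that("radius estimation recovers synthetic plates", {
  tpl <- episode_config(true_radius = 100, seed = 30)
  ep_cal <- generate_episode(tpl, cam)
  prof <- make_profile(ep_cal, 100)
  tab <- build_line_table(cam$focal_length_mm,
                          distance_band_mm = table_band_for_profile(prof),
                          n_pairs = 2000, seed = 3)

  # self-test on the calibration plate's own sequence
  est_self <- estimate_radius(ep_cal$observations, cam, prof, tab)
  expect_lt(abs(est_self$estimated_radius - 100) / 100, 0.05)
  expect_true(all(est_self$p_curve$P >= 0 & est_self$p_curve$P <= 1))

  # unknown 120 mm plate drawn from the same environment
  cfg2 <- tpl; cfg2$true_radius <- 120; cfg2$seed <- 31
  ep2 <- generate_episode(cfg2, cam)
  est <- estimate_radius(ep2$observations, cam, prof, tab)
  expect_lt(abs(est$estimated_radius - 120), 5)
  expect_equal(est$estimated_radius, est$gaussian_mean)  # no clamping here

  # fitted Gaussian explains the noise-free P curve
  pc <- est$p_curve
  fitted <- est$gaussian_amplitude *
    exp(-(pc$R_t - est$gaussian_mean)^2 / (2 * est$gaussian_sd^2))
  r2 <- 1 - sum((pc$P - fitted)^2) / sum((pc$P - mean(pc$P))^2)
  expect_gte(r2, 0.8)
})

test_that("sequences inconsistent with the calibration range are rejected", {
  tpl <- episode_config(true_radius = 100, seed = 32)
  prof <- make_profile(generate_episode(tpl, cam), 100)
  tab <- build_line_table(cam$focal_length_mm, n_pairs = 300, seed = 3)
  far_cfg <- episode_config(true_radius = 100, n_frames = 12,
                            base_distance = 9000, oscillation_amplitude = 100,
                            distance_jitter_sd = 0, seed = 33)
  far <- generate_episode(far_cfg, cam)
  expect_error(estimate_radius(far$observations, cam, prof, tab),
               "out-of-calibration-range")
})

test_that("estimates scale with the true radius", {
  tpl <- episode_config(true_radius = 100, seed = 40)
  prof <- make_profile(generate_episode(tpl, cam), 100)
  tab <- build_line_table(cam$focal_length_mm,
                          distance_band_mm = table_band_for_profile(prof),
                          n_pairs = 2000, seed = 3)
  base <- estimate_radius(generate_episode(tpl, cam)$observations, cam,
                          prof, tab)$estimated_radius
  for (k in c(0.75, 1.25)) {
    cfg <- tpl; cfg$true_radius <- 100 * k
    est <- estimate_radius(generate_episode(cfg, cam)$observations, cam,
                           prof, tab)$estimated_radius
    expect_lt(abs(est - k * base) / (k * base), 0.05)
  }
})
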