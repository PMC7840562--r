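cam <- test_cam()

test_that("histogram trimming removes sparse extreme bins in one pass", {
  # uniform counts: nothing trimmed
  d <- rep(seq(400, 490, by = 10), each = 2)
  expect_equal(trim_distance_range(d, bins = 10), range(d))
  # one far value in the top bin: 1 < 0.5 * (21/10)
  d <- c(runif(20, 400, 500), 900)
  set.seed(1); d <- c(runif(20, 400, 500), 900)
  expect_equal(trim_distance_range(d, bins = 10), brute_trim(d, 10))
  expect_equal(trim_distance_range(d, bins = 10)[2], max(d[d < 900]))
  # both extreme bins sparse, trimmed in the same pass
  d <- c(100, runif(30, 400, 500), 900)
  expect_equal(trim_distance_range(d, bins = 10), brute_trim(d, 10))
  expect_equal(trim_distance_range(d, bins = 10),
               range(d[d > 100 & d < 900]))
  expect_error(trim_distance_range(rep(5, 4)), "zero-width")
})

test_that("trimming matches a brute-force oracle on random lists", {
  set.seed(202)
  for (i in 1:60) {
    kind <- i %% 3
    d <- if (kind == 0) runif(sample(20:80, 1), 300, 600)
         else if (kind == 1) rnorm(sample(20:80, 1), 450, 60)
         else c(rnorm(40, 450, 30), runif(sample(1:3, 1), 700, 900))
    bins <- sample(5:12, 1)
    expect_equal(trim_distance_range(d, bins), brute_trim(d, bins))
  }
})

test_that("trimming keeps at least half of the data inside the input range", {
  set.seed(303)
  for (i in 1:40) {
    d <- c(rnorm(50, 450, 40), runif(sample(0:4, 1), 650, 900))
    rng <- trim_distance_range(d, 10)
    expect_gte(rng[1], min(d)); expect_lte(rng[2], max(d))
    kept <- d[d >= rng[1] & d <= rng[2]]
    expect_gte(length(kept), length(d) / 2)
  }
})

test_that("trimming is idempotent on clustered data with isolated outliers", {
  # dense, evenly filled core bins plus sparse extremes: the single pass
  # removes the extremes and a second pass finds nothing below half of
  # the average frequency
  for (out in list(c(900), c(120, 900, 950), numeric(0))) {
    d <- c(rep(seq(400, 500, by = 5), each = 3), out)
    rng <- trim_distance_range(d, 10)
    kept <- d[d >= rng[1] & d <= rng[2]]
    expect_equal(trim_distance_range(kept, 10), rng)
  }
})

test_that("distance series matches synthetic ground truth frame by frame", {
  cfg <- episode_config(true_radius = 100, n_frames = 24, seed = 4)
  ep <- generate_episode(cfg, cam)
  ser <- compute_distance_series(ep$observations, cam, 100)
  expect_equal(nrow(ser), 24)
  expect_equal(ser$D, ep$ground_truth$distance, tolerance = 1e-6)
  # single fronto-parallel frame
  one <- data.frame(frame = 0L, cx = 0, cy = 0, a = 3 * 100 / 400,
                    b = 3 * 100 / 400, theta = 0)
  expect_equal(compute_distance_series(one, cam, 100)$D, 400,
               tolerance = 1e-9)
  # a frame the solver cannot use is dropped, not fatal
  bad <- rbind(ep$observations, data.frame(frame = 99L, cx = 0, cy = 0,
                                           a = 0.5, b = -1, theta = 0))
  expect_warning(ser2 <- compute_distance_series(bad, cam, 100), "dropped")
  expect_equal(nrow(ser2), nrow(bad) - 1)
})

test_that("calibration recovers the true distance range", {
  # jitter-free sinusoid: distances span [300, 600] exactly
  cfg <- episode_config(true_radius = 100, n_frames = 48, base_distance = 450,
                        oscillation_amplitude = 150, oscillation_period = 12,
                        distance_jitter_sd = 0, seed = 6)
  ep <- generate_episode(cfg, cam)
  prof <- calibrate(ep$observations, cam, 100, bins = 10)
  bin_w <- (600 - 300) / 10
  expect_lt(abs(prof$D_lower - 300), bin_w)
  expect_lt(abs(prof$D_upper - 600), bin_w)
  expect_equal(prof$n_frames_used, 48)

  # far-distance outlier frames do not widen the profile
  far <- generate_episode(episode_config(true_radius = 100, n_frames = 2,
                                         base_distance = 1200,
                                         oscillation_amplitude = 0,
                                         distance_jitter_sd = 0, seed = 8),
                          cam)
  both <- rbind(ep$observations, far$observations)
  prof2 <- calibrate(both, cam, 100, bins = 10)
  wide_bin <- (1200 - 300) / 10
  expect_lt(abs(prof2$D_upper - prof$D_upper), wide_bin)

  # two frames only: range is the two values
  two <- ep$observations[c(3, 9), ]
  prof3 <- calibrate(two, cam, 100)
  expect_equal(prof3$n_frames_used, 2)
  d2 <- compute_distance_series(two, cam, 100)$D
  expect_equal(c(prof3$D_lower, prof3$D_upper), sort(d2))
})

test_that("calibration profiles serialize to JSON and back", {
  prof <- structure(list(reference_radius = 100, D_lower = 310, D_upper = 580,
                         n_frames_used = 48L, histogram_bins = 10L,
                         camera_id = "ebutton-01", created_from = "meal-3"),
                    class = "calibration_profile")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_calibration_profile(prof, path)
  prof2 <- read_calibration_profile(path)
  expect_equal(prof2$D_lower, 310)
  expect_equal(prof2$reference_radius, 100)
  expect_equal(prof2$camera_id, "ebutton-01")
})
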