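cam <- test_cam()

test_that("pixel records convert to image-plane millimeters", {
  raw <- data.frame(frame = 0L, center_x_px = 640, center_y_px = 480,
                    a_px = 200, b_px = 100, theta_deg = 270)
  obs <- pixels_to_image_plane(raw, cam)
  expect_equal(obs$a, 0.6)                    # 200 px * 0.003 mm/px
  expect_equal(obs$b, 0.3)
  expect_equal(obs$cx, 0)                     # center at principal point
  expect_equal(obs$cy, 0)
  expect_equal(obs$theta, pi / 2)             # 3*pi/2 folds to pi/2
  expect_error(pixels_to_image_plane(transform(raw, a_px = -1), cam),
               "non-positive semi-axes")
  # round trip through the pixel layout
  back <- image_plane_to_pixels(obs, cam)
  expect_equal(back$a_px, raw$a_px)
  expect_equal(back$center_x_px, raw$center_x_px)
})

test_that("geometric and conic forms are mutual inverses", {
  # axis-aligned ellipse: diagonal quadratic part with ratio b^2/a^2
  Q <- geometric_to_conic(ellipse_obs(0, 0, 2, 1))
  expect_equal(Q[1, 2], 0)
  expect_equal(Q[1, 1] / Q[2, 2], 1 / 4)
  # unit circle: proportional to diag(1, 1, -1)
  Qc <- geometric_to_conic(ellipse_obs(0, 0, 1, 1))
  expect_equal(Qc, diag(c(1, 1, -1)), tolerance = 1e-12)

  set.seed(101)
  for (i in 1:50) {
    e <- ellipse_obs(runif(1, -2, 2), runif(1, -2, 2),
                     a <- runif(1, 0.5, 3), runif(1, 0.1, 1) * a,
                     runif(1, 0, pi))
    r <- conic_to_geometric(geometric_to_conic(e))
    expect_equal(r$cx, e$cx, tolerance = 1e-10)
    expect_equal(r$cy, e$cy, tolerance = 1e-10)
    expect_equal(r$a, e$a, tolerance = 1e-10)
    expect_equal(r$b, e$b, tolerance = 1e-10)
    if (e$a / e$b > 1.001) {
      expect_lt(platescale:::fold_angle_diff(r$theta - e$theta), 1e-10)
    }
  }
})

test_that("degenerate conics are rejected", {
  # two intersecting lines x^2 - y^2 = 0: indefinite quadratic part
  Q <- diag(c(1, -1, 0))
  expect_error(conic_to_geometric(Q), "not_an_ellipse")
  # imaginary ellipse x^2 + y^2 + 1 = 0
  expect_error(conic_to_geometric(diag(c(1, 1, 1))), "not_an_ellipse")
})

test_that("fronto-parallel circles project by similar triangles", {
  e <- project_circle(circle_pose(c(0, 0, 400), c(0, 0, 1), 100), cam)
  expect_equal(e$a, 3 * 100 / 400, tolerance = 1e-12)
  expect_equal(e$b, e$a, tolerance = 1e-12)
  expect_equal(e$cx, 0, tolerance = 1e-12)
  expect_error(project_circle(circle_pose(c(0, 200, 1), c(0, 1, 0), 100), cam),
               "degenerate|in front")
})

test_that("projected ellipse contains the images of sampled circle points", {
  set.seed(7)
  for (i in 1:10) {
    rp <- random_pose()
    e <- project_circle(rp$pose, cam)
    Q <- geometric_to_conic(e)
    b <- platescale:::plane_basis(rp$pose$normal)
    phi <- seq(0, 2 * pi, length.out = 361)[-361]
    resid <- vapply(phi, function(p) {
      x <- rp$pose$center + rp$pose$radius * (cos(p) * b$u + sin(p) * b$v)
      q <- c(cam$focal_length_mm * x[1] / x[3],
             cam$focal_length_mm * x[2] / x[3], 1)
      abs(drop(t(q) %*% Q %*% q)) / (sum(Q^2)^0.5 * sum(q^2))
    }, numeric(1))
    expect_lt(max(resid), 1e-9)
  }
})

test_that("distance recovery inverts projection over the operating envelope", {
  # fronto-parallel special case: exact inversion
  e <- ellipse_obs(0, 0, 3 * 100 / 400, 3 * 100 / 400)
  sol <- distance_from_ellipse(e, cam, 100)
  expect_equal(sol$distance_D, 400, tolerance = 1e-12)
  expect_equal(sol$ambiguity_count, 1L)

  set.seed(11)
  for (i in 1:200) {
    rp <- random_pose()
    e <- project_circle(rp$pose, cam)
    sol <- distance_from_ellipse(e, cam, rp$R)
    expect_equal(sol$distance_D, rp$D, tolerance = 1e-6)
    # contract: reported distance equals the norm of the recovered center
    expect_equal(sol$distance_D, sqrt(sum(sol$pose$center^2)),
                 tolerance = 1e-9)
  }
})

test_that("distance is exactly homogeneous in the candidate radius", {
  set.seed(13)
  for (i in 1:20) {
    rp <- random_pose()
    e <- project_circle(rp$pose, cam)
    d1 <- distance_from_ellipse(e, cam, rp$R)$distance_D
    d2 <- distance_from_ellipse(e, cam, 2 * rp$R)$distance_D
    dk <- distance_from_ellipse(e, cam, 0.37 * rp$R)$distance_D
    expect_equal(d2, 2 * d1, tolerance = 1e-12)
    expect_equal(dk, 0.37 * d1, tolerance = 1e-12)
  }
})

test_that("distance is invariant under image rotation about the principal point", {
  set.seed(17)
  for (i in 1:20) {
    rp <- random_pose()
    e <- project_circle(rp$pose, cam)
    d0 <- distance_from_ellipse(e, cam, rp$R)$distance_D
    rot <- runif(1, 0, 2 * pi)
    cr <- cos(rot); sr <- sin(rot)
    er <- ellipse_obs(cr * e$cx - sr * e$cy, sr * e$cx + cr * e$cy,
                      e$a, e$b, e$theta + rot)
    dr <- distance_from_ellipse(er, cam, rp$R)$distance_D
    expect_equal(dr, d0, tolerance = 1e-9)
  }
})
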