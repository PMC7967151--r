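test_that("Savitzky-Golay smoothing preserves polynomials and damps noise", {
  h <- seq(0, 200, by = 5)
  const <- ankleproj:::world_profile(h, rep(1800, length(h)))
  expect_equal(smooth_profile(const)$depth_mm, const$depth_mm, tolerance = 1e-9)
  lin <- ankleproj:::world_profile(h, 1500 + 2 * h)
  expect_equal(smooth_profile(lin)$depth_mm, lin$depth_mm, tolerance = 1e-9)

  set.seed(5)
  clean <- 1800 + 30 * sin(h / 30)
  noisy <- clean + rnorm(length(h), 0, 5)
  sm <- smooth_profile(ankleproj:::world_profile(h, noisy))
  expect_lt(sqrt(mean((sm$depth_mm - clean)^2)),
            sqrt(mean((noisy - clean)^2)))
  expect_true(sm$smoothed)

  short <- ankleproj:::world_profile(1:3 * 10, c(1, 2, 3))
  expect_warning(smooth_profile(short), "too short")
})

test_that("chord rotation equalizes endpoint depths and preserves distances", {
  flat <- ankleproj:::world_profile(c(0, 100, 200), c(1500, 1550, 1500))
  rot <- rotate_profile(flat)
  expect_equal(rot$beta_deg, 0)
  expect_equal(rot$depth_mm, flat$depth_mm)

  p <- ankleproj:::world_profile(c(0, 150, 400), c(0, 80, 100))
  rot <- rotate_profile(p)
  expect_equal(rot$beta_deg, 14.036, tolerance = 1e-3)
  expect_equal(rot$height_mm[3], 412.31, tolerance = 1e-2)
  expect_lt(abs(rot$depth_mm[3] - rot$depth_mm[1]), 1e-6)
  # isometry: all pairwise distances preserved
  dist0 <- dist(cbind(p$height_mm, p$depth_mm))
  dist1 <- dist(cbind(rot$height_mm, rot$depth_mm))
  expect_lt(max(abs(dist0 - dist1)), 1e-6)

  degen <- ankleproj:::world_profile(c(0, 0), c(100, 100))
  expect_error(rotate_profile(degen), "coincide")
})

test_that("ankle localization picks the interior deepest point", {
  p <- ankleproj:::world_profile(c(0, 10, 20, 30, 40), c(0, 50, 120, 80, 0))
  expect_identical(locate_ankle(p), 3L)   # 1-based sample index
  # a wedge built with its vertex at a known sample
  w <- make_wedge(90, n_foot = 16, n_leg = 23)
  rot <- rotate_profile(w$profile)
  expect_identical(locate_ankle(rot), w$ankle_index)
  # maximal plateau resolves to its middle
  p2 <- ankleproj:::world_profile(seq(0, 60, by = 10),
                                  c(0, 50, 90, 90, 90, 40, 0))
  expect_identical(locate_ankle(p2), 4L)
  mono <- ankleproj:::world_profile(c(0, 10, 20, 30), c(0, 10, 20, 30))
  expect_error(locate_ankle(mono), "degenerate")
})

test_that("two-segment regression recovers wedge interior angles", {
  # perpendicular arms
  w <- make_wedge(90)
  est <- ankle_angle_from_profile(rotate_profile(w$profile))
  expect_equal(est$angle_deg, 90, tolerance = 0.5)
  # collinear profile split at its midpoint
  h <- seq(0, 100, by = 5)
  line <- ankleproj:::world_profile(h, 1500 - 0.4 * h)
  est <- ankle_angle_from_profile(line, ankle = 11L)
  expect_equal(est$angle_deg, 180)
  # a family of wedge angles
  for (ang in c(70, 75, 90, 105, 120)) {
    w <- make_wedge(ang, n_foot = 30, n_leg = 40)
    est <- ankle_angle_from_profile(rotate_profile(w$profile))
    expect_equal(est$angle_deg, ang, tolerance = 0.5)
    expect_gt(est$r2_foot, 0.99)
    expect_gt(est$r2_leg, 0.99)
  }
  expect_error(ankle_angle_from_profile(make_wedge(90)$profile, ankle = 1L),
               "interior")
})

test_that("profile angle is invariant to rigid translation and scaling", {
  w <- make_wedge(82, n_foot = 18, n_leg = 27)
  base <- ankle_angle_from_profile(rotate_profile(w$profile))$angle_deg
  sh <- w$profile
  sh$height_mm <- sh$height_mm + 123.4
  sh$depth_mm <- sh$depth_mm - 777
  expect_equal(ankle_angle_from_profile(rotate_profile(sh))$angle_deg, base,
               tolerance = 1e-6)
  sc <- w$profile
  sc$height_mm <- sc$height_mm * 3.7
  sc$depth_mm <- sc$depth_mm * 3.7
  expect_equal(ankle_angle_from_profile(rotate_profile(sc))$angle_deg, base,
               tolerance = 1e-6)
})

test_that("three-point angle follows the scalar-product formula", {
  a <- world_point(0, 0, 0)
  expect_equal(three_point_angle(world_point(0, 400, 0), a,
                                 world_point(0, 0, -150)), 90)
  expect_equal(three_point_angle(world_point(0, 400, 0), a,
                                 world_point(0, -50, 150)), 108.43,
               tolerance = 1e-2)
  # scale invariance and knee/foot symmetry
  k <- world_point(0, 380, 25); f <- world_point(0, -40, 160)
  g0 <- three_point_angle(k, a, f)
  k2 <- world_point(0, 380 * 7, 25 * 7)
  expect_equal(three_point_angle(k2, a, f), g0, tolerance = 1e-9)
  expect_equal(three_point_angle(f, a, k), g0, tolerance = 1e-9)
  expect_error(three_point_angle(a, a, f), "zero-length")
})
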