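# construct a pair with an exact Pearson correlation
exact_r_pair <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- scale(rnorm(n))[, 1]
  e <- scale(resid(lm(rnorm(n) ~ x)))[, 1]
  y <- r * x + sqrt(1 - r^2) * e
  list(x = x, y = y)
}

as_pairs <- function(x, y) {
  p <- data.frame(time_s = seq_along(x), method_a_deg = x, method_b_deg = y)
  attr(p, "lag_s") <- 0; attr(p, "n") <- nrow(p)
  class(p) <- c("paired_angles", "data.frame")
  p
}

test_that("nearest-timestamp pairing handles identical and lagged grids", {
  t <- seq(0, 5, by = 1 / 30)
  a <- angle_series(t, 90 + 10 * sin(t), method = "projected_line")
  b <- angle_series(t, 90 + 10 * sin(t), method = "imu")
  p <- pair_series(a, b, max_gap_s = 0.01)
  expect_equal(attr(p, "lag_s"), 0)
  expect_equal(nrow(p), length(t))

  # b delayed by 0.3 s: the lag search recovers it within one sample period
  tb <- seq(0, 5, by = 0.01)
  b2 <- angle_series(tb + 0.3, 90 + 10 * sin(tb), method = "imu")
  p2 <- pair_series(a, b2, max_gap_s = 0.05)
  expect_lt(abs(attr(p2, "lag_s") - (-0.3)), 0.011)
  err <- max(abs(p2$method_a_deg - p2$method_b_deg))
  expect_lt(err, 0.5)

  c2 <- angle_series(tb + 100, 90 + 10 * sin(tb), method = "imu")
  expect_error(pair_series(a, c2, max_gap_s = 0.05), "fewer than 4")
})

test_that("Fisher-Z intervals match the hand-computed reference", {
  pr <- exact_r_pair(0.9, 103)
  cc <- correlations(as_pairs(pr$x, pr$y))
  expect_equal(cc$pearson_r, 0.9, tolerance = 1e-10)
  # se = 1/sqrt(100) = 0.1, z-space half-width 1.95996 * 0.1
  expect_equal(cc$pearson_lo, tanh(atanh(0.9) - 0.195996), tolerance = 1e-6)
  expect_equal(cc$pearson_hi, tanh(atanh(0.9) + 0.195996), tolerance = 1e-6)
  expect_equal(round(cc$pearson_lo, 3), 0.855)
  expect_equal(round(cc$pearson_hi, 3), 0.931)

  x <- 1:50
  cc <- correlations(as_pairs(x, exp(x / 10)))
  expect_equal(cc$spearman_rho, 1)
  expect_lt(cc$pearson_r, 1)

  lin <- correlations(as_pairs(1:20, 2 * (1:20) + 3))
  expect_equal(lin$pearson_r, 1)
  expect_equal(c(lin$pearson_lo, lin$pearson_hi), c(1, 1))
  expect_error(correlations(as_pairs(rep(1, 10), 1:10)), "constant")
})

test_that("correlation and error metrics equal naive textbook formulas", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(10:1000, 1)
    x <- rnorm(n, 90, 15); y <- 0.8 * x + rnorm(n, 0, 10)
    p <- as_pairs(x, y)
    cc <- correlations(p)
    r_naive <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    rx <- rank(x); ry <- rank(y)
    rho_naive <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_lt(abs(cc$pearson_r - r_naive), 1e-12)
    expect_lt(abs(cc$spearman_rho - rho_naive), 1e-12)
    em <- rmse_mae(p)
    expect_lt(abs(em[["rmse_deg"]] - sqrt(sum((x - y)^2) / n)), 1e-12)
    expect_lt(abs(em[["mae_deg"]] - sum(abs(x - y)) / n), 1e-12)
    expect_lte(em[["mae_deg"]], em[["rmse_deg"]])
    # interval always brackets the estimate
    expect_lte(cc$pearson_lo, cc$pearson_r)
    expect_gte(cc$pearson_hi, cc$pearson_r)
  }
})

test_that("interval width shrinks as 1/sqrt(n - 3)", {
  widths <- sapply(c(28, 103, 403), function(n) {
    pr <- exact_r_pair(0.7, n, seed = 2)
    cc <- correlations(as_pairs(pr$x, pr$y))
    atanh(cc$pearson_hi) - atanh(cc$pearson_lo)
  })
  expect_equal(widths[1] / widths[2], sqrt(100 / 25), tolerance = 1e-6)
  expect_equal(widths[2] / widths[3], sqrt(400 / 100), tolerance = 1e-6)
})

test_that("error metrics reproduce hand-worked values", {
  p <- as_pairs(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(unname(rmse_mae(p)), c(0, 0))
  p <- as_pairs(c(0, 0, 5, 5), c(3, 4, 5, 5))
  expect_equal(rmse_mae(p)[["rmse_deg"]], sqrt(25 / 4), tolerance = 1e-12)
  expect_equal(rmse_mae(p)[["mae_deg"]], 7 / 4, tolerance = 1e-12)
})

test_that("sensor depth-error model is the published linear law", {
  expect_equal(depth_error(0), 0.0253)
  expect_equal(depth_error(2), 0.0513)
  z <- seq(0, 4.5, by = 0.1)
  expect_true(all(diff(depth_error(z)) > 0))
  expect_error(depth_error(-1), ">= 0")
})

test_that("angle uncertainty matches a Richardson-extrapolated derivative", {
  # alpha(z) itself at a hand-computed point
  expect_equal(ankleproj:::angle_from_z(400, -50, 100), 102.53, tolerance = 1e-2)
  expect_equal(angle_error(400, -50, 100, dz_mm = 0), 0)

  richardson <- function(f, z) {
    h <- 1
    d1 <- (f(z + h) - f(z - h)) / (2 * h)
    h2 <- h / 2
    d2 <- (f(z + h2) - f(z - h2)) / (2 * h2)
    (4 * d2 - d1) / 3
  }
  for (case in list(c(400, -50, 100), c(350, -80, 500), c(420, -60, 1500))) {
    f <- function(z) ankleproj:::angle_from_z(case[1], case[2], z)
    expected <- abs(richardson(f, case[3])) * depth_error(case[3] / 1000) * 1000
    got <- angle_error(case[1], case[2], case[3])
    expect_lt(abs(got / expected - 1), 0.001)
  }

  # far field: cos approaches 1 and the angle decays monotonically
  a <- sapply(c(2000, 4000, 8000, 16000),
              function(z) ankleproj:::angle_from_z(400, 50, z))
  expect_true(all(diff(a) < 0))
  expect_error(angle_error(0, 50, 100), "nonzero")
})
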