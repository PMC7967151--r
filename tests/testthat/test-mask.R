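rgb_blank <- function() matrix(FALSE, 1080, 1920)
depth_blank <- function() matrix(0, 424, 512)

test_that("mask transfer maps overlap pixels and drops the rest", {
  m <- body_mask(rgb_blank(), "rgb")
  expect_equal(sum(transfer_mask(m)$grid), 0)

  g <- rgb_blank(); g[541, 977] <- TRUE    # pixel (x = 976, y = 540)
  out <- transfer_mask(body_mask(g, "rgb"))
  expect_identical(which(out$grid, arr.ind = TRUE)[1, ],
                   c(row = 213L, col = 257L))  # depth pixel (256, 212)

  g <- rgb_blank(); g[541, 101] <- TRUE    # x = 100 < 220: outside overlap
  expect_equal(sum(transfer_mask(body_mask(g, "rgb"))$grid), 0)
  expect_error(transfer_mask(body_mask(depth_blank() > 1, "depth")), "RGB")
})

test_that("mask cleaning applies the -700/+300 mm body window", {
  g <- depth_blank() > 1
  g[100:110, 200:210] <- TRUE
  d <- depth_blank(); d[g] <- 2000
  res <- clean_mask(body_mask(g, "depth"), depth_frame(d))
  expect_equal(res$mean_depth_mm, 2000)
  expect_equal(sum(res$mask$grid), sum(g))   # window [1300, 2300] keeps all

  d[100, 200:203] <- c(1900, 2100, 2500, 0)  # one outlier, one invalid
  res <- clean_mask(body_mask(g, "depth"), depth_frame(d))
  dd <- d[g]
  expect_equal(res$mean_depth_mm, mean(dd[dd > 0]))
  expect_false(res$mask$grid[100, 202])      # 2500 above dbar + 300
  expect_false(res$mask$grid[100, 203])      # invalid dropped
  expect_true(res$mask$grid[100, 200])

  expect_error(clean_mask(body_mask(depth_blank() > 1, "depth"),
                          depth_frame(depth_blank())), "empty")
})

test_that("cleaned mask is a subset and its mean stays inside the window", {
  set.seed(42)
  g <- depth_blank() > 1
  g[cbind(sample(424, 300, TRUE), sample(512, 300, TRUE))] <- TRUE
  d <- depth_blank(); d[g] <- rnorm(sum(g), 2000, 600)
  d[d < 0] <- 0
  res <- clean_mask(body_mask(g, "depth"), depth_frame(d))
  expect_true(all(g[res$mask$grid]))
  kept <- d[res$mask$grid]
  expect_true(mean(kept) >= res$mean_depth_mm - 700)
  expect_true(mean(kept) <= res$mean_depth_mm + 300)
})

test_that("height factor interpolates the distance table and clamps", {
  expect_equal(height_factor(1500), 0.75)
  expect_equal(height_factor(2500), 0.85)   # midway between 0.8 and 0.9
  expect_equal(height_factor(5000), 0.95)
  expect_equal(height_factor(100), 0.65)
  # monotone non-decreasing over the physical range
  f <- height_factor(seq(100, 6000, by = 50))
  expect_true(all(diff(f) >= 0))
  expect_error(height_factor(-1), "positive")
})

test_that("leg selection keeps the requested side below the height limit", {
  g <- depth_blank() > 1
  g[100:300, 240:260] <- TRUE               # single leg column block
  m <- body_mask(g, "depth")
  leg <- select_leg(m, 2000, side = "auto", f = 0.5)
  expect_identical(leg$lim_row, 99L + as.integer(round(0.5 * 201)))
  idx <- which(leg$mask$grid, arr.ind = TRUE)
  expect_true(all(idx[, "row"] - 1 >= leg$lim_row))

  g2 <- g; g2[100:300, 340:360] <- TRUE     # second leg to the right
  left <- select_leg(body_mask(g2, "depth"), 2000, side = "left", f = 0.5)
  expect_true(all(which(left$mask$grid, arr.ind = TRUE)[, "col"] <= 300))
  right <- select_leg(body_mask(g2, "depth"), 2000, side = "right", f = 0.5)
  expect_true(all(which(right$mask$grid, arr.ind = TRUE)[, "col"] >= 300))
  # auto keeps the larger connected component
  g3 <- g2; g3[100:300, 341:360] <- FALSE   # shrink the right leg
  auto <- select_leg(body_mask(g3, "depth"), 2000, side = "auto", f = 0.5)
  expect_true(all(which(auto$mask$grid, arr.ind = TRUE)[, "col"] <= 260))

  expect_error(select_leg(m, 2000, f = 1), "empty")
})

test_that("projection line reads bottom-to-top along the deepest-run column", {
  g <- depth_blank() > 1
  g[200:240, 250] <- TRUE                   # single-column region
  d <- depth_blank(); d[200:240, 250] <- seq(2000, 1900, length.out = 41)
  region <- select_leg(body_mask(g, "depth"), 2000, f = 0)
  prof <- extract_projection_line(region, depth_frame(d))
  expect_identical(prof$col, 249L)          # zero-based column
  expect_true(all(diff(prof$row) < 0))      # strictly decreasing rows
  expect_equal(prof$depth_mm[1], 1900)      # bottom-most row first
  expect_equal(prof$depth_mm[41], 2000)
  expect_true(all(g[cbind(prof$row + 1L, prof$col + 1L)]))
})

test_that("projection line interpolates short gaps and enforces min length", {
  g <- depth_blank() > 1
  g[200:240, 250] <- TRUE
  d <- depth_blank(); d[200:240, 250] <- 2000
  d[220, 250] <- 0                          # isolated invalid return
  region <- select_leg(body_mask(g, "depth"), 2000, f = 0)
  prof <- extract_projection_line(region, depth_frame(d))
  expect_equal(length(prof$depth_mm), 41)
  expect_equal(prof$depth_mm[which(prof$row == 219L)], 2000)
  # a long gap truncates the profile instead
  d[215:220, 250] <- 0
  prof2 <- extract_projection_line(region, depth_frame(d))
  expect_true(all(prof2$row >= 220L))

  g2 <- depth_blank() > 1
  g2[200:202, 250] <- TRUE
  d2 <- depth_blank(); d2[200:202, 250] <- 2000
  region2 <- select_leg(body_mask(g2, "depth"), 2000, f = 0)
  expect_error(extract_projection_line(region2, depth_frame(d2)), "too short")
})
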