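#' Synthetic articulated-leg scene specification
#'
#' Parameters of a synthetic lower-leg/foot depth scene with known ground
#' truth. The limb is modelled as two capsules (cylinders with
#' hemispherical caps) meeting at the ankle in the sagittal (y-z) plane:
#' the shank rises from the ankle toward the knee, the foot extends from
#' the ankle toward the camera. The interior angle between the two capsule
#' axes is the true ankle angle.
#'
#' `ankle_angle_deg` and `leg_tilt_deg` may be constants or functions of
#' time (seconds) for moving trajectories. The default kinematics are
#' foot-flat: the ankle angle is produced by tilting the shank over a
#' horizontal foot (`tilt = 90 - angle`), which is how knee-bend and
#' stance-phase dorsiflexion happen on a planted foot; passing
#' `leg_tilt_deg` explicitly decouples the shank tilt (the foot pitch then
#' absorbs the remainder of the angle). By default the ankle sits below
#' the optical axis at `-0.45 * distance * tan(vfov/2)`, emulating a
#' camera mounted above ankle height, so the per-pixel rays descend and
#' graze the instep the way they do in real recordings.
#'
#' @param distance_mm Ankle distance from the camera, mm (500-4500).
#' @param ankle_angle_deg True ankle angle (deg), constant or `function(t)`;
#'   values must stay within (10, 350).
#' @param leg_length_mm,foot_length_mm,limb_radius_mm Limb dimensions, mm.
#' @param frame_rate_hz,duration_s Camera frame rate and clip length.
#' @param depth_noise_sigma_mm Gaussian depth noise per pixel, mm.
#' @param clock_distortion `NULL`, or `list(c = , k = )` parameters of the
#'   saturating recording-lag model applied to the IMU timestamps:
#'   recorded interval i is stretched to `dt * (1 + c * i / (i + k))`.
#' @param leg_tilt_deg Forward tilt of the shank toward the camera (deg),
#'   constant or `function(t)`; `NULL` (default) selects foot-flat
#'   kinematics.
#' @param ankle_y_mm Height of the ankle relative to the optical axis, mm;
#'   `NULL` for the default framing above.
#' @param two_legs Render a second, vertical contralateral leg offset in x
#'   (for leg-selection tests).
#' @param leg_sep_mm Centre-to-centre x offset of the second leg.
#' @param seed Integer seed controlling all scene randomness.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(distance_mm = 2000, ankle_angle_deg = 90,
                       leg_length_mm = 400, foot_length_mm = 220,
                       limb_radius_mm = 50, frame_rate_hz = 30,
                       duration_s = 1, depth_noise_sigma_mm = 0,
                       clock_distortion = NULL, leg_tilt_deg = NULL,
                       ankle_y_mm = NULL, two_legs = FALSE,
                       leg_sep_mm = 200, seed = 1L) {
  stopifnot(distance_mm >= 500, distance_mm <= 4500,
            leg_length_mm > 0, foot_length_mm > 0, limb_radius_mm > 0,
            frame_rate_hz > 0, duration_s > 0, depth_noise_sigma_mm >= 0)
  structure(list(distance_mm = distance_mm, ankle_angle_deg = ankle_angle_deg,
                 leg_length_mm = leg_length_mm, foot_length_mm = foot_length_mm,
                 limb_radius_mm = limb_radius_mm, frame_rate_hz = frame_rate_hz,
                 duration_s = duration_s,
                 depth_noise_sigma_mm = depth_noise_sigma_mm,
                 clock_distortion = clock_distortion,
                 leg_tilt_deg = leg_tilt_deg, ankle_y_mm = ankle_y_mm,
                 two_legs = isTRUE(two_legs), leg_sep_mm = leg_sep_mm,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

as_time_fun <- function(x) if (is.function(x)) x else function(t) rep(x, length(t))

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Lattice of surface points of the capsule from p0 to p1 with radius r:
# cylinder rings every `step` mm along the axis and around the
# circumference, plus quasi-uniform (Fibonacci) spherical caps at the ends.
sample_capsule <- function(p0, p1, r, step) {
  u <- p1 - p0
  len <- sqrt(sum(u^2))
  u <- u / len
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- cross3(u, a); n1 <- n1 / sqrt(sum(n1^2))
  n2 <- cross3(u, n1)
  tt <- seq(0, len, by = step)
  nphi <- max(8L, ceiling(2 * pi * r / step))
  phi <- seq(0, 2 * pi, length.out = nphi + 1L)[-(nphi + 1L)]
  gr <- expand.grid(t = tt, phi = phi)
  circ <- r * (cos(gr$phi) %o% n1 + sin(gr$phi) %o% n2)
  cyl <- cbind(p0[1] + gr$t * u[1], p0[2] + gr$t * u[2], p0[3] + gr$t * u[3]) + circ
  ns <- max(64L, ceiling(4 * pi * r^2 / step^2))
  i <- seq_len(ns)
  ga <- pi * (3 - sqrt(5))
  zz <- 1 - 2 * (i - 0.5) / ns
  rr <- sqrt(pmax(0, 1 - zz^2))
  dirs <- cbind(rr * cos(ga * i), rr * sin(ga * i), zz)
  caps <- rbind(sweep(r * dirs, 2, p0, "+"), sweep(r * dirs, 2, p1, "+"))
  rbind(cyl, caps)
}

scene_keypoints_world <- function(spec, t) {
  th <- as_time_fun(spec$ankle_angle_deg)(t)
  tilt <- if (is.null(spec$leg_tilt_deg)) 90 - th
  else as_time_fun(spec$leg_tilt_deg)(t)
  if (any(th <= 10 | th >= 350)) stop("ankle angle trajectory outside (10, 350)")
  z0 <- spec$distance_mm
  y0 <- if (is.null(spec$ankle_y_mm))
    -0.45 * z0 * tan(deg2rad(ir_intrinsics()$vfov_deg) / 2) else spec$ankle_y_mm
  tau <- deg2rad(tilt)
  leg_dir <- cbind(0, cos(tau), -sin(tau))        # shank: ankle -> knee
  foot_ang <- tau + deg2rad(th)
  foot_dir <- cbind(0, cos(foot_ang), -sin(foot_ang))  # ankle -> toe
  n <- length(t)
  list(
    ankle = cbind(x = rep(0, n), y = rep(y0, n), z = rep(z0, n)),
    knee = cbind(x = 0, y = y0 + spec$leg_length_mm * leg_dir[, 2],
                 z = z0 + spec$leg_length_mm * leg_dir[, 3]),
    toe = cbind(x = 0, y = y0 + spec$foot_length_mm * foot_dir[, 2],
                z = z0 + spec$foot_length_mm * foot_dir[, 3]),
    angle_deg = th, tilt_deg = tilt
  )
}

render_one_frame <- function(spec, kp, i, ir, map, sigma) {
  r <- spec$limb_radius_mm
  # lattice step below the pixel footprint at the nearest limb point, so
  # the rasterized silhouette has no holes
  z_near <- min(kp$ankle[i, "z"], kp$knee[i, "z"], kp$toe[i, "z"]) - r
  step <- min(6, max(0.3, 0.55 * z_near *
                       tan(deg2rad(ir$hfov_deg) / 2) / (ir$width_px / 2)))
  pts <- rbind(
    sample_capsule(kp$ankle[i, ], kp$knee[i, ], r, step),
    sample_capsule(kp$ankle[i, ], kp$toe[i, ], r, step))
  if (spec$two_legs) {
    off <- c(spec$leg_sep_mm, 0, 0)
    pts <- rbind(pts,
                 sample_capsule(kp$ankle[i, ] + off, kp$knee[i, ] + off, r, step),
                 sample_capsule(kp$ankle[i, ] + off, kp$toe[i, ] + off, r, step))
  }
  pts <- pts[pts[, 3] > 10, , drop = FALSE]
  px <- world_to_depth_pixel(pts[, 1], pts[, 2], pts[, 3], ir)
  ci <- as.integer(round(px$col)); ri <- as.integer(round(px$row))
  keep <- ci >= 0L & ci < ir$width_px & ri >= 0L & ri < ir$height_px
  if (!any(keep)) stop("limb outside the camera field of view")
  ci <- ci[keep]; ri <- ri[keep]; z <- pts[keep, 3]
  o <- order(z, decreasing = TRUE)         # nearest depth assigned last wins
  grid <- matrix(0, ir$height_px, ir$width_px)
  grid[cbind(ri[o] + 1L, ci[o] + 1L)] <- z[o]
  if (sigma > 0) {
    nz <- which(grid > 0)
    grid[nz] <- pmax(grid[nz] + stats::rnorm(length(nz), 0, sigma), 1)
  }
  grid
}

#' Render a synthetic depth-scene sequence with ground truth
#'
#' Produces, for each frame, a depth image of the capsule leg/foot model
#' (surface points forward-projected through the camera model with
#' nearest-depth z-buffering and optional seeded Gaussian depth noise), a
#' body mask in RGB space (the depth silhouette mapped through the inverse
#' pixel registration), projected knee/ankle/toe keypoints in RGB
#' coordinates, and the per-frame ground truth. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [scene_spec()].
#' @param ir,map Camera model ([ir_intrinsics()], [overlap_limits()]).
#' @return A list: `frames` (list of [depth_frame()]), `masks` (list of
#'   RGB-space [body_mask()]), `keypoints` (data.frame with RGB pixel
#'   coordinates per frame and `source = "synthetic"`), `truth`
#'   (data.frame: `time_s`, `angle_deg`, `tilt_deg`, world knee/ankle/toe
#'   y and z, `distance_mm`), and `spec`.
#' @export
render_scene <- function(spec, ir = ir_intrinsics(), map = overlap_limits()) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  n <- max(1L, round(spec$duration_s * spec$frame_rate_hz))
  times <- (seq_len(n) - 1) / spec$frame_rate_hz
  kp <- scene_keypoints_world(spec, times)
  frames <- vector("list", n)
  masks <- vector("list", n)
  kp_rows <- vector("list", n)
  for (i in seq_len(n)) {
    grid <- render_one_frame(spec, kp, i, ir, map, spec$depth_noise_sigma_mm)
    frames[[i]] <- depth_frame(grid, times[i])
    dsil <- which(grid > 0, arr.ind = TRUE)
    rp <- depth_to_rgb_pixel(dsil[, "col"] - 1L, dsil[, "row"] - 1L, map)
    mg <- matrix(FALSE, map$rgb_height_px, map$rgb_width_px)
    for (dx in -1:1) for (dy in -1:1) {
      xr <- as.integer(round(rp$x)) + dx
      yr <- as.integer(round(rp$y)) + dy
      ok <- xr >= 0L & xr < map$rgb_width_px & yr >= 0L & yr < map$rgb_height_px
      mg[cbind(yr[ok] + 1L, xr[ok] + 1L)] <- TRUE
    }
    masks[[i]] <- body_mask(mg, "rgb", times[i])
    one_kp <- function(w) {
      dp <- world_to_depth_pixel(w[1], w[2], w[3], ir)
      rg <- depth_to_rgb_pixel(dp$col, dp$row, map)
      c(rg$x, rg$y)
    }
    kn <- one_kp(kp$knee[i, ]); an <- one_kp(kp$ankle[i, ]); to <- one_kp(kp$toe[i, ])
    kp_rows[[i]] <- data.frame(frame = i, timestamp_s = times[i],
                               knee_x = kn[1], knee_y = kn[2],
                               ankle_x = an[1], ankle_y = an[2],
                               foot_x = to[1], foot_y = to[2],
                               source = "synthetic")
  }
  truth <- data.frame(time_s = times, angle_deg = kp$angle_deg,
                      tilt_deg = kp$tilt_deg,
                      knee_y_mm = kp$knee[, "y"], knee_z_mm = kp$knee[, "z"],
                      ankle_y_mm = kp$ankle[, "y"], ankle_z_mm = kp$ankle[, "z"],
                      toe_y_mm = kp$toe[, "y"], toe_z_mm = kp$toe[, "z"],
                      distance_mm = spec$distance_mm)
  list(frames = frames, masks = masks,
       keypoints = do.call(rbind, kp_rows), truth = truth, spec = spec)
}

#' Synthesize the two IMU pitch streams for a scene
#'
#' Inverts the ankle-angle relation `theta = 180 - alpha + beta`: the leg
#' unit reads `alpha = 90 + tilt` and the foot unit
#' `beta = theta - 180 + alpha`, so the combined angle reproduces the
#' ground-truth trajectory exactly at the sample times. Pitch is sampled
#' on the ideal 100 Hz grid; if the scene requests clock distortion, the
#' recorded timestamps are warped by the saturating-lag model
#' `dt_i = dt * (1 + c * i / (i + k))` while the values stay on the ideal
#' grid, emulating a host that stores samples too slowly.
#'
#' @param truth Truth table from [render_scene()] (only the duration is
#'   used; pitch is re-evaluated from the spec's trajectories).
#' @param spec The [scene_spec()].
#' @param rate_hz IMU sampling rate.
#' @return A list of two [imu_stream()]s, `leg` and `foot` (uncorrected
#'   when distortion is active).
#' @export
synth_imu <- function(truth, spec, rate_hz = 100) {
  stopifnot(inherits(spec, "scene_spec"))
  t <- seq(0, spec$duration_s, by = 1 / rate_hz)
  th <- as_time_fun(spec$ankle_angle_deg)(t)
  tilt <- if (is.null(spec$leg_tilt_deg)) 90 - th
  else as_time_fun(spec$leg_tilt_deg)(t)
  alpha <- 90 + tilt
  beta <- th - 180 + alpha
  ts <- t
  if (!is.null(spec$clock_distortion)) {
    cd <- spec$clock_distortion
    i <- seq_len(length(t) - 1)
    dt <- (1 / rate_hz) * (1 + cd$c * i / (i + cd$k))
    ts <- c(t[1], t[1] + cumsum(dt))
  }
  list(leg = imu_stream(ts, alpha, nominal_rate_hz = rate_hz,
                        corrected = FALSE),
       foot = imu_stream(ts, beta, nominal_rate_hz = rate_hz,
                         corrected = FALSE))
}
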