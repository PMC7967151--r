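#' Convert a pixel-space projection profile to world millimetres
#'
#' Each (row, depth) sample along the scan column is mapped through
#' [depth_pixel_to_world()]; the profile becomes an ordered sequence of
#' (height_mm, depth_mm) pairs in camera-centred coordinates, foot end
#' first, with heights increasing up the leg.
#'
#' @param p A pixel-space `projection_profile` from
#'   [extract_projection_line()].
#' @param ir Depth-camera [camera_intrinsics()].
#' @return A world-space `projection_profile` with fields `height_mm` and
#'   `depth_mm`.
#' @export
as_world_profile <- function(p, ir = ir_intrinsics()) {
  stopifnot(inherits(p, "projection_profile"))
  if (p$units != "pixel") return(p)
  w <- depth_pixel_to_world(p$col, p$row, p$depth_mm, ir)
  structure(list(height_mm = w$y_mm, depth_mm = w$z_mm, col = p$col,
                 timestamp_s = p$timestamp_s,
                 smoothed = p$smoothed, beta_deg = p$beta_deg,
                 units = "world"),
            class = "projection_profile")
}

world_profile <- function(height_mm, depth_mm, timestamp_s = NA_real_,
                          smoothed = FALSE, beta_deg = 0) {
  structure(list(height_mm = height_mm, depth_mm = depth_mm, col = NA_integer_,
                 timestamp_s = timestamp_s, smoothed = smoothed,
                 beta_deg = beta_deg, units = "world"),
            class = "projection_profile")
}

#' Smooth a projection profile with a Savitzky-Golay filter
#'
#' Replaces the depth values by their local least-squares polynomial fit
#' (which preserves polynomial signals up to the fit order exactly);
#' heights are left untouched. The window is shrunk to the largest valid
#' odd value not exceeding the profile length when necessary; if no window
#' larger than the polynomial order fits, the profile is passed through
#' with a warning.
#'
#' @param p A world-space `projection_profile`.
#' @param window Odd filter window length (samples).
#' @param order Polynomial order, `< window`.
#' @return The profile with filtered depths and `smoothed = TRUE`.
#' @export
smooth_profile <- function(p, window = 11L, order = 3L) {
  stopifnot(inherits(p, "projection_profile"), p$units == "world")
  n <- length(p$depth_mm)
  w <- min(window, if (n %% 2 == 1) n else n - 1L)
  if (w %% 2 == 0) w <- w - 1L
  if (w <= order) {
    warning("profile too short for Savitzky-Golay smoothing; passed through")
    p$smoothed <- TRUE
    return(p)
  }
  p$depth_mm <- as.numeric(signal::sgolayfilt(p$depth_mm, p = order, n = w))
  p$smoothed <- TRUE
  p
}

#' Rotate a profile so foot and leg ends are at the same depth
#'
#' Rigidly rotates the (height, depth) samples about the foot endpoint F by
#' `beta = atan2(depth(L) - depth(F), height(L) - height(F))` so that the
#' leg endpoint L comes to the same depth as F. After rotation the ankle is
#' the deepest point of the curve regardless of the camera's position
#' relative to the leg.
#'
#' @param p A world-space `projection_profile` (at least 2 samples).
#' @return The rotated profile; `beta_deg` records the applied angle.
#' @export
rotate_profile <- function(p) {
  stopifnot(inherits(p, "projection_profile"), p$units == "world")
  n <- length(p$depth_mm)
  if (n < 2) stop("need at least 2 samples to rotate")
  h <- p$height_mm - p$height_mm[1]
  d <- p$depth_mm - p$depth_mm[1]
  if (abs(h[n]) < 1e-12 && abs(d[n]) < 1e-12)
    stop("foot and leg endpoints coincide")
  beta <- atan2(d[n], h[n])
  p$height_mm <- p$height_mm[1] + cos(beta) * h + sin(beta) * d
  p$depth_mm <- p$depth_mm[1] - sin(beta) * h + cos(beta) * d
  p$beta_deg <- p$beta_deg + rad2deg(beta)
  p
}

#' Locate the ankle on a rotated profile
#'
#' The ankle is the deepest point of the chord-rotated curve: the index of
#' maximal depth strictly between the endpoints. A plateau of equal maxima
#' yields its middle index. A maximum at an endpoint means the frame has no
#' interior kink (degenerate) and raises an error so the caller can drop
#' the frame.
#'
#' @param p A rotated world-space `projection_profile`.
#' @param tol Depth tolerance (mm) for plateau detection.
#' @return Integer index (1-based) of the ankle sample.
#' @export
locate_ankle <- function(p, tol = 1e-9) {
  stopifnot(inherits(p, "projection_profile"), p$units == "world")
  d <- p$depth_mm
  n <- length(d)
  mx <- max(d)
  at <- which(d >= mx - tol)
  runs <- split(at, cumsum(c(1, diff(at) != 1)))
  # the plateau containing the global maximum
  main <- runs[[which.max(vapply(runs, function(r) max(d[r]), numeric(1)))]]
  idx <- main[ceiling(length(main) / 2)]
  if (idx <= 1L || idx >= n)
    stop("degenerate profile: deepest point at an endpoint")
  idx
}

segment_fit <- function(h, d) {
  # least-squares line depth ~ height; returns slope and R^2
  fit <- stats::lm.fit(cbind(1, h), d)
  slope <- fit$coefficients[2]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((d - mean(d))^2)
  r2 <- if (ss_tot < 1e-12) 1 else 1 - ss_res / ss_tot
  list(slope = unname(slope), r2 = r2)
}

arc_trim <- function(h, d, trim) {
  if (trim <= 0 || length(h) <= 4) return(list(h = h, d = d))
  s <- c(0, cumsum(sqrt(diff(h)^2 + diff(d)^2)))
  keep <- s >= trim * max(s) & s <= (1 - trim) * max(s)
  if (sum(keep) < 2) return(list(h = h, d = d))
  list(h = h[keep], d = d[keep])
}

#' Ankle angle from a rotated projection profile
#'
#' Fits one least-squares line to the foot segment (foot end to ankle) and
#' one to the leg segment (ankle to leg end) in (height, depth) world
#' millimetres, and reports the interior angle at the ankle between the two
#' fitted directions, in (0, 180] degrees.
#'
#' Two refinements keep the fits on the straight parts of the curve. With
#' `foot_from_crest = TRUE` the foot fit starts at the toe crest — the
#' shallowest rotated sample before the ankle — so the near-vertical front
#' face of the toe, whose surface is orthogonal to the foot axis, does not
#' enter the foot line. `trim` removes that fraction of each segment's arc
#' length from both of its ends before fitting, which excludes the rounded
#' ankle corner (the soft-tissue radius around the joint) from both lines.
#' On an ideal two-line wedge profile both refinements are no-ops.
#'
#' @param p A rotated world-space `projection_profile`.
#' @param ankle Ankle sample index from [locate_ankle()]; strictly
#'   interior. The ankle sample belongs to both segments.
#' @param foot_from_crest Start the foot fit at the shallowest rotated
#'   sample (the toe crest) instead of the profile's first sample.
#' @param trim Fraction of each segment's arc length dropped from each of
#'   its ends before fitting (0 fits the full segments).
#' @return An `ankle_estimate` object: `angle_deg`, `ankle_index`,
#'   `slope_foot`, `slope_leg`, `r2_foot`, `r2_leg`.
#' @export
ankle_angle_from_profile <- function(p, ankle = locate_ankle(p),
                                     foot_from_crest = TRUE, trim = 0.15) {
  stopifnot(inherits(p, "projection_profile"), p$units == "world")
  n <- length(p$depth_mm)
  if (ankle <= 1L || ankle >= n) stop("ankle index must be strictly interior")
  start <- 1L
  if (foot_from_crest) {
    crest <- which.min(p$depth_mm[seq_len(ankle)])
    if (crest < ankle - 1L) start <- crest
  }
  foot <- start:ankle
  leg <- ankle:n
  if (length(foot) < 2 || length(leg) < 2) stop("segment with fewer than 2 samples")
  fs <- arc_trim(p$height_mm[foot], p$depth_mm[foot], trim)
  ls <- arc_trim(p$height_mm[leg], p$depth_mm[leg], trim)
  ff <- segment_fit(fs$h, fs$d)
  lf <- segment_fit(ls$h, ls$d)
  # directions away from the ankle: foot points down the profile, leg up
  v1 <- c(-1, -ff$slope)
  v2 <- c(1, lf$slope)
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  ang <- rad2deg(acos(max(-1, min(1, cosang))))
  if (ang == 0) ang <- 180  # collinear degenerate maps to the open-interval top
  structure(list(angle_deg = ang, ankle_index = ankle,
                 slope_foot = ff$slope, slope_leg = lf$slope,
                 r2_foot = ff$r2, r2_leg = lf$r2),
            class = "ankle_estimate")
}

#' @export
print.ankle_estimate <- function(x, ...) {
  cat(sprintf("ankle_estimate: %.2f deg at sample %d (R2 foot %.3f, leg %.3f)\n",
              x$angle_deg, x$ankle_index, x$r2_foot, x$r2_leg))
  invisible(x)
}

#' Three-keypoint ankle angle
#'
#' The sagittal-plane angle at the ankle between the knee and foot
#' keypoints, from the scalar product of the vectors ankle-to-knee and
#' ankle-to-foot using their (z, y) components only:
#' `gamma = arccos[(z1 z2 + y1 y2) / (|v1| |v2|)]` in degrees.
#'
#' @param knee,ankle,foot [world_point()]s (or lists with `y_mm`, `z_mm`).
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' three_point_angle(world_point(0, 400, 0), world_point(0, 0, 0),
#'                   world_point(0, 0, -150))  # 90
#' @export
three_point_angle <- function(knee, ankle, foot) {
  z1 <- knee$z_mm - ankle$z_mm; y1 <- knee$y_mm - ankle$y_mm
  z2 <- foot$z_mm - ankle$z_mm; y2 <- foot$y_mm - ankle$y_mm
  n1 <- sqrt(z1^2 + y1^2); n2 <- sqrt(z2^2 + y2^2)
  if (n1 < 1e-12 || n2 < 1e-12) stop("zero-length limb vector")
  rad2deg(acos(max(-1, min(1, (z1 * z2 + y1 * y2) / (n1 * n2)))))
}
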