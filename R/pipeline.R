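#' Projection-line ankle angles for a frame sequence
#'
#' Runs the full projection-line pipeline on each (depth frame, mask)
#' pair: RGB masks are registered into depth space, cleaned by the depth
#' window, restricted to the lower leg, and the scan-column profile is
#' converted to world millimetres, Savitzky-Golay smoothed, chord-rotated,
#' and split at its deepest point into the two regression segments whose
#' interior angle is the ankle angle. Frames on which any stage degenerates
#' (empty mask, too-short profile, no interior deepest point) are skipped
#' and logged, not fatal.
#'
#' The per-frame uncertainty is the propagated depth error
#' ([angle_error()]) evaluated at the fitted segment extents and the mean
#' body distance.
#'
#' @param frames List of [depth_frame()]s.
#' @param masks List of [body_mask()]s (RGB or depth space), same length
#'   and order.
#' @param map,ir Camera model.
#' @param side Leg side passed to [select_leg()].
#' @param f Height factor; `NULL` means look up [height_factor()] at each
#'   frame's mean depth (appropriate for whole-body masks). For lower-leg-
#'   only scenes pass the calibrated fraction directly.
#' @param window,order Savitzky-Golay parameters.
#' @return An [angle_series()] (`method = "projected_line"`) with
#'   attribute `skipped`: data.frame of skipped frame indices and reasons.
#' @export
profile_angle_series <- function(frames, masks, map = overlap_limits(),
                                 ir = ir_intrinsics(), side = "auto",
                                 f = NULL, window = 11L, order = 3L) {
  stopifnot(length(frames) == length(masks))
  if (length(frames) == 0) stop("empty input")
  ts <- angs <- sigs <- numeric(0)
  skipped <- list()
  for (i in seq_along(frames)) {
    res <- tryCatch({
      mask <- masks[[i]]
      if (mask$space == "rgb") mask <- transfer_mask(mask, map)
      cl <- clean_mask(mask, frames[[i]])
      fr <- if (is.null(f)) height_factor(cl$mean_depth_mm) else f
      leg <- select_leg(cl$mask, cl$mean_depth_mm, side = side, f = fr)
      prof <- extract_projection_line(leg, frames[[i]])
      prof <- as_world_profile(prof, ir)
      prof <- smooth_profile(prof, window = window, order = order)
      prof <- rotate_profile(prof)
      ai <- locate_ankle(prof)
      est <- ankle_angle_from_profile(prof, ai)
      n <- length(prof$height_mm)
      yk <- prof$height_mm[n] - prof$height_mm[ai]
      yf <- prof$height_mm[1] - prof$height_mm[ai]
      sig <- tryCatch(
        angle_error(yk, yf, cl$mean_depth_mm, body_z_m = cl$mean_depth_mm / 1000),
        error = function(e) NA_real_)
      list(t = frames[[i]]$timestamp_s, a = est$angle_deg, s = sig)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(frame = i, reason = conditionMessage(res))
    } else {
      ts <- c(ts, res$t); angs <- c(angs, res$a); sigs <- c(sigs, res$s)
    }
  }
  if (length(angs) == 0) stop("no frame produced an ankle angle")
  out <- angle_series(ts, angs, ifelse(is.na(sigs), 0, sigs),
                      method = "projected_line")
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(frame = integer(0), reason = character(0))
  out
}

#' Three-keypoint ankle angles for a frame sequence
#'
#' The comparator route used by skeleton or pose-estimation inputs: each
#' frame's knee/ankle/foot keypoints (RGB pixel coordinates) are
#' registered into depth space, their range read from the depth frame,
#' lifted to world coordinates, and combined by the scalar-product angle
#' ([three_point_angle()]). Frames where any keypoint falls outside the
#' overlap or on an invalid depth pixel are skipped and logged.
#'
#' @param keypoints Data.frame with one row per frame: `timestamp_s`,
#'   `knee_x`, `knee_y`, `ankle_x`, `ankle_y`, `foot_x`, `foot_y` (RGB
#'   pixel coordinates).
#' @param frames List of [depth_frame()]s, same length and order.
#' @param map,ir Camera model.
#' @return An [angle_series()] (`method = "three_point"`) with attribute
#'   `skipped` as in [profile_angle_series()].
#' @export
keypoint_angle_series <- function(keypoints, frames, map = overlap_limits(),
                                  ir = ir_intrinsics()) {
  stopifnot(nrow(keypoints) == length(frames))
  if (length(frames) == 0) stop("empty input")
  ts <- angs <- sigs <- numeric(0)
  skipped <- list()
  lift <- function(x, y, frame) {
    p <- rgb_to_depth_pixel(x, y, map)
    if (!p$inside) stop("keypoint outside the camera overlap")
    ci <- as.integer(round(p$x)); ri <- as.integer(round(p$y))
    if (ci < 0 || ci >= map$ir_width_px || ri < 0 || ri >= map$ir_height_px)
      stop("keypoint outside the depth image")
    d <- frame$grid[ri + 1L, ci + 1L]
    if (d <= 0) stop("keypoint on an invalid depth pixel")
    w <- depth_pixel_to_world(ci, ri, d, ir)
    world_point(w$x_mm, w$y_mm, w$z_mm)
  }
  for (i in seq_len(nrow(keypoints))) {
    k <- keypoints[i, ]
    res <- tryCatch({
      kn <- lift(k$knee_x, k$knee_y, frames[[i]])
      an <- lift(k$ankle_x, k$ankle_y, frames[[i]])
      ft <- lift(k$foot_x, k$foot_y, frames[[i]])
      ang <- three_point_angle(kn, an, ft)
      sig <- tryCatch(
        angle_error(kn$y_mm - an$y_mm, ft$y_mm - an$y_mm, an$z_mm),
        error = function(e) NA_real_)
      list(t = k$timestamp_s, a = ang, s = sig)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(frame = i, reason = conditionMessage(res))
    } else {
      ts <- c(ts, res$t); angs <- c(angs, res$a); sigs <- c(sigs, res$s)
    }
  }
  if (length(angs) == 0) stop("no frame produced an ankle angle")
  out <- angle_series(ts, angs, ifelse(is.na(sigs), 0, sigs),
                      method = "three_point")
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(frame = integer(0), reason = character(0))
  out
}
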