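#' Camera intrinsics
#'
#' Bundle of the parameters describing one camera of an integrated RGB +
#' depth device: sensor resolution, focal length expressed in millimetres on
#' the focal plane, and the horizontal/vertical angles of view. The
#' `baseline_shift_mm` field is the horizontal offset to the paired camera
#' (48 mm for the reference device).
#'
#' @param width_px,height_px Sensor resolution in pixels.
#' @param focal_len_mm Focal length in mm.
#' @param hfov_deg,vfov_deg Horizontal and vertical angle of view in degrees,
#'   each in (0, 180).
#' @param baseline_shift_mm Horizontal offset to the paired camera in mm.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' ir_intrinsics()
#' camera_intrinsics(1920, 1080, 3291, 84.7, 54.36)
#' @export
camera_intrinsics <- function(width_px, height_px, focal_len_mm,
                              hfov_deg, vfov_deg, baseline_shift_mm = 48) {
  stopifnot(width_px > 0, height_px > 0, focal_len_mm > 0)
  if (!(hfov_deg > 0 && hfov_deg < 180 && vfov_deg > 0 && vfov_deg < 180))
    stop("angles of view must lie strictly between 0 and 180 degrees")
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    focal_len_mm = focal_len_mm, hfov_deg = hfov_deg, vfov_deg = vfov_deg,
    baseline_shift_mm = baseline_shift_mm
  ), class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: %d x %d px, f = %g mm, fov %g x %g deg\n",
              x$width_px, x$height_px, x$focal_len_mm, x$hfov_deg, x$vfov_deg))
  invisible(x)
}

#' Reference device intrinsics
#'
#' Intrinsics of the reference integrated RGB-D device: the colour camera is
#' 1920 x 1080 px with focal length 3291 mm and 84.7 x 54.36 degree fields
#' of view; the depth (IR time-of-flight) camera is 512 x 424 px with focal
#' length 3657 mm and 70 x 60.2 degree fields of view. The cameras are
#' 48 mm apart horizontally.
#'
#' @return A `camera_intrinsics` object.
#' @export
rgb_intrinsics <- function() {
  camera_intrinsics(1920L, 1080L, 3291, 84.7, 54.36, baseline_shift_mm = 48)
}

#' @rdname rgb_intrinsics
#' @export
ir_intrinsics <- function() {
  camera_intrinsics(512L, 424L, 3657, 70, 60.2, baseline_shift_mm = 48)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Physical size of the focal plane
#'
#' Width and height, in mm, of the virtual plane at the focal distance on
#' which pixel extents correspond to physical lengths: each dimension is
#' `2 * f * tan(fov / 2)`, the intersection of the two boundary view rays
#' with the plane at distance `f`.
#'
#' @param cam A [camera_intrinsics()] object.
#' @return Named numeric vector `c(width_mm, height_mm)`.
#' @examples
#' round(focal_plane_dims(ir_intrinsics()) / 10) * 10  # 5120 x 4240 mm
#' @export
focal_plane_dims <- function(cam) {
  stopifnot(inherits(cam, "camera_intrinsics"))
  w <- 2 * cam$focal_len_mm * tan(deg2rad(cam$hfov_deg) / 2)
  h <- 2 * cam$focal_len_mm * tan(deg2rad(cam$vfov_deg) / 2)
  if (!is.finite(w) || !is.finite(h)) stop("non-finite focal plane size")
  c(width_mm = w, height_mm = h)
}

#' Pixel point in RGB or depth image space
#'
#' Image coordinates follow the top-left-origin convention: `x` is the
#' column (rightward), `y` the row (downward), both zero-based and
#' real-valued.
#'
#' @param x,y Column and row coordinate.
#' @param space Either `"rgb"` or `"depth"`.
#' @return A `pixel_point` object.
#' @export
pixel_point <- function(x, y, space = c("rgb", "depth")) {
  space <- match.arg(space)
  stopifnot(is.finite(x), is.finite(y))
  structure(list(x = x, y = y, space = space), class = "pixel_point")
}

#' Camera-centred world point
#'
#' Millimetre coordinates centred on the camera: x rightward, y upward,
#' z away from the camera along the optical axis.
#'
#' @param x_mm,y_mm,z_mm Coordinates in mm; `z_mm >= 0` for physical points.
#' @return A `world_point` object.
#' @export
world_point <- function(x_mm, y_mm, z_mm) {
  stopifnot(is.finite(x_mm), is.finite(y_mm), is.finite(z_mm))
  structure(list(x_mm = x_mm, y_mm = y_mm, z_mm = z_mm), class = "world_point")
}

#' RGB-to-depth overlap map
#'
#' Because the colour camera is wider than the depth camera, only a central
#' band of RGB columns has depth counterparts. `overlap_limits()` derives,
#' from the two cameras' focal-plane half-widths, the published registration
#' constants: the half-span of overlapping RGB columns, the left/right RGB
#' column limits, the per-pixel physical pitch on the RGB focal plane, the
#' baseline correction in RGB pixels, and the depth-row images of the top
#' and bottom RGB rows.
#'
#' The published pipeline works with view half-angles rounded to whole
#' degrees (42 and 35 for the reference devices), truncates the
#' focal-plane half-width ratio to two decimals, and rounds its product
#' with the RGB half-resolution to the nearest ten pixels; that arithmetic
#' is reproduced by default so the reference constants (740, 220, 1700,
#' 3 mm/px, 16 px) are hit exactly. With `exact_ratio = TRUE` the exact
#' half-angles and untruncated ratio are used instead.
#'
#' The vertical constants (depth rows 21 and 403 as the images of RGB rows
#' 0 and 1080) are the published calibration values for the reference
#' device and are not re-derived; override them for other devices.
#'
#' @param rgb,ir [camera_intrinsics()] for the colour and depth cameras.
#' @param exact_ratio Use the exact half-width ratio instead of the
#'   published truncate-then-round arithmetic.
#' @param y_top_ir_px,y_bottom_ir_px Depth-row images of RGB rows 0 and
#'   `rgb$height_px`.
#' @return An `overlap_map` object with fields `x_halfwidth_px`,
#'   `x_left_px`, `x_right_px`, `x_shift_px`, `pitch_mm_per_px`,
#'   `y_top_ir_px`, `y_bottom_ir_px`, plus the resolutions it maps between.
#' @examples
#' m <- overlap_limits()
#' c(m$x_halfwidth_px, m$x_left_px, m$x_right_px, m$x_shift_px)
#' @export
overlap_limits <- function(rgb = rgb_intrinsics(), ir = ir_intrinsics(),
                           exact_ratio = FALSE,
                           y_top_ir_px = 21L, y_bottom_ir_px = 403L) {
  stopifnot(inherits(rgb, "camera_intrinsics"), inherits(ir, "camera_intrinsics"))
  if (ir$hfov_deg >= rgb$hfov_deg)
    stop("unsupported configuration: depth camera horizontally wider than RGB")
  half_rgb <- rgb$width_px / 2
  half_ang <- function(fov) if (exact_ratio) fov / 2 else round(fov / 2)
  h <- rgb$focal_len_mm * tan(deg2rad(half_ang(rgb$hfov_deg)))  # RGB half-width, mm
  hp <- rgb$focal_len_mm * tan(deg2rad(half_ang(ir$hfov_deg)))  # IR half-width on same plane
  if (exact_ratio) {
    halfwidth <- round(half_rgb * hp / h)
  } else {
    ratio <- trunc(hp / h * 100) / 100
    halfwidth <- round(half_rgb * ratio / 10) * 10
  }
  pitch <- round(h / half_rgb)
  shift <- round(rgb$baseline_shift_mm / pitch)
  structure(list(
    x_halfwidth_px = as.integer(halfwidth),
    x_left_px = as.integer(half_rgb - halfwidth),
    x_right_px = as.integer(half_rgb + halfwidth),
    x_shift_px = as.integer(shift),
    pitch_mm_per_px = as.integer(pitch),
    y_top_ir_px = as.integer(y_top_ir_px),
    y_bottom_ir_px = as.integer(y_bottom_ir_px),
    rgb_width_px = rgb$width_px, rgb_height_px = rgb$height_px,
    ir_width_px = ir$width_px, ir_height_px = ir$height_px
  ), class = "overlap_map")
}

#' @export
print.overlap_map <- function(x, ...) {
  cat(sprintf(
    "overlap_map: RGB cols [%d, %d] <-> depth cols [0, %d], shift %d px (%d mm/px)\n",
    x$x_left_px, x$x_right_px, x$ir_width_px, x$x_shift_px, x$pitch_mm_per_px))
  cat(sprintf("  RGB rows [0, %d] -> depth rows [%d, %d]\n",
              x$rgb_height_px, x$y_top_ir_px, x$y_bottom_ir_px))
  invisible(x)
}

#' Map RGB pixel coordinates to depth pixel coordinates
#'
#' Applies the affine column and row registration
#' `x_IR = (x_RGB - x_left - shift) * w_IR / (x_right - x_left)` and
#' `y_IR = y_top + y_RGB * (y_bottom - y_top) / h_RGB`. Coordinates are
#' kept real-valued; round to the nearest pixel only at lookup time.
#' Inputs outside the overlap band are mapped anyway and flagged.
#'
#' @param x,y RGB pixel coordinates (vectors allowed), or a
#'   [pixel_point()] in `x` with `y` missing.
#' @param map An [overlap_limits()] map.
#' @return A data.frame with columns `x`, `y` (depth coordinates) and
#'   `inside` (logical, whether the source pixel has a depth counterpart).
#' @examples
#' rgb_to_depth_pixel(976, 540)  # -> (256, 212), centre of the depth image
#' @export
rgb_to_depth_pixel <- function(x, y, map = overlap_limits()) {
  if (inherits(x, "pixel_point")) {
    if (x$space != "rgb") stop("pixel_point must be in rgb space")
    y <- x$y; x <- x$x
  }
  span <- map$x_right_px - map$x_left_px
  xi <- (x - map$x_left_px - map$x_shift_px) * map$ir_width_px / span
  yi <- map$y_top_ir_px +
    y * (map$y_bottom_ir_px - map$y_top_ir_px) / map$rgb_height_px
  inside <- xi >= 0 & xi <= map$ir_width_px &
    y >= 0 & y <= map$rgb_height_px
  data.frame(x = xi, y = yi, inside = inside)
}

#' Map depth pixel coordinates back to RGB pixel coordinates
#'
#' Algebraic inverse of [rgb_to_depth_pixel()].
#'
#' @inheritParams rgb_to_depth_pixel
#' @return A data.frame with columns `x` and `y` in RGB coordinates.
#' @export
depth_to_rgb_pixel <- function(x, y, map = overlap_limits()) {
  span <- map$x_right_px - map$x_left_px
  xr <- x * span / map$ir_width_px + map$x_left_px + map$x_shift_px
  yr <- (y - map$y_top_ir_px) * map$rgb_height_px /
    (map$y_bottom_ir_px - map$y_top_ir_px)
  data.frame(x = xr, y = yr)
}

#' Convert a depth pixel to camera-centred world coordinates
#'
#' For a depth pixel at column `col`, row `row` (top-left origin, zero
#' based) holding range `depth_mm`, the world position follows from similar
#' triangles on the focal plane: with centred coordinates
#' `x' = col - w/2` and `y' = h/2 - row` (y positive up),
#' `x = x' * z * tan(hfov/2) / (w/2)` and `y = y' * z * tan(vfov/2) / (h/2)`,
#' and `z = depth_mm`. The image centre maps to `x = y = 0`.
#'
#' @param col,row Depth pixel coordinates (vectors allowed).
#' @param depth_mm Range value(s) in mm, `>= 0`.
#' @param ir Depth-camera [camera_intrinsics()].
#' @return A data.frame with columns `x_mm`, `y_mm`, `z_mm`.
#' @examples
#' depth_pixel_to_world(256, 212, 1500)  # centre -> (0, 0, 1500)
#' @export
depth_pixel_to_world <- function(col, row, depth_mm, ir = ir_intrinsics()) {
  if (any(depth_mm < 0)) stop("negative depth")
  cx <- ir$width_px / 2
  cy <- ir$height_px / 2
  xp <- col - cx
  yp <- cy - row
  z <- depth_mm
  data.frame(
    x_mm = xp * z * tan(deg2rad(ir$hfov_deg) / 2) / cx,
    y_mm = yp * z * tan(deg2rad(ir$vfov_deg) / 2) / cy,
    z_mm = z
  )
}

#' Project camera-centred world coordinates to depth pixel coordinates
#'
#' Algebraic inverse of [depth_pixel_to_world()]; requires `z_mm > 0`.
#'
#' @param x_mm,y_mm,z_mm World coordinates in mm (vectors allowed).
#' @param ir Depth-camera [camera_intrinsics()].
#' @return A data.frame with real-valued columns `col` and `row`.
#' @export
world_to_depth_pixel <- function(x_mm, y_mm, z_mm, ir = ir_intrinsics()) {
  if (any(z_mm <= 0)) stop("z must be positive to project")
  cx <- ir$width_px / 2
  cy <- ir$height_px / 2
  data.frame(
    col = cx + x_mm * cx / (z_mm * tan(deg2rad(ir$hfov_deg) / 2)),
    row = cy - y_mm * cy / (z_mm * tan(deg2rad(ir$vfov_deg) / 2))
  )
}

#' Read or write a camera configuration file
#'
#' A JSON key/value file with optional `rgb`, `ir` (intrinsics overrides)
#' and `overlap` (constant overrides) blocks; absent keys fall back to the
#' reference device values.
#'
#' @param path Path to a JSON config file, or `NULL` for pure defaults.
#' @return A list with elements `rgb`, `ir` ([camera_intrinsics()]) and
#'   `map` ([overlap_limits()]).
#' @export
camera_config <- function(path = NULL) {
  rgb <- rgb_intrinsics(); ir <- ir_intrinsics()
  ov <- list()
  if (!is.null(path)) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    mod <- function(base, over) {
      for (k in names(over)) base[[k]] <- over[[k]]
      do.call(camera_intrinsics, base[c("width_px", "height_px", "focal_len_mm",
                                        "hfov_deg", "vfov_deg", "baseline_shift_mm")])
    }
    if (!is.null(cfg$rgb)) rgb <- mod(unclass(rgb), cfg$rgb)
    if (!is.null(cfg$ir)) ir <- mod(unclass(ir), cfg$ir)
    if (!is.null(cfg$overlap)) ov <- cfg$overlap
  }
  map <- do.call(overlap_limits, c(list(rgb = rgb, ir = ir), ov))
  list(rgb = rgb, ir = ir, map = map)
}
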