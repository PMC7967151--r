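#' Body mask
#'
#' A binary silhouette of the detected body, either in RGB image space
#' (1080 x 1920 for the reference device) or in depth image space
#' (424 x 512), stored rows x columns with top-left origin.
#'
#' @param grid Logical or 0/1 matrix, rows x columns.
#' @param space `"rgb"` or `"depth"`.
#' @param timestamp_s Frame timestamp in seconds.
#' @return A `body_mask` object.
#' @export
body_mask <- function(grid, space = c("rgb", "depth"), timestamp_s = NA_real_) {
  space <- match.arg(space)
  grid <- matrix(as.logical(grid), nrow = nrow(grid), ncol = ncol(grid))
  structure(list(grid = grid, space = space, timestamp_s = timestamp_s),
            class = "body_mask")
}

#' @export
print.body_mask <- function(x, ...) {
  cat(sprintf("body_mask [%s]: %d x %d px, %d set pixels\n", x$space,
              nrow(x$grid), ncol(x$grid), sum(x$grid)))
  invisible(x)
}

#' Depth frame
#'
#' One 424 x 512 grid of range values in mm; 0 encodes an invalid pixel
#' (no time-of-flight return).
#'
#' @param grid Numeric matrix of ranges in mm (values `>= 0`).
#' @param timestamp_s Frame timestamp in seconds.
#' @return A `depth_frame` object.
#' @export
depth_frame <- function(grid, timestamp_s = NA_real_) {
  if (any(grid < 0)) stop("depth values must be >= 0")
  structure(list(grid = grid, timestamp_s = timestamp_s), class = "depth_frame")
}

#' Transfer an RGB-space mask to depth space
#'
#' Each set RGB pixel inside the camera-overlap band is mapped through the
#' column/row registration ([rgb_to_depth_pixel()]) and rounded to its
#' nearest depth pixel; RGB pixels outside the overlap are dropped.
#'
#' @param mask A [body_mask()] in RGB space.
#' @param map An [overlap_limits()] map.
#' @return A [body_mask()] in depth space (424 x 512 for the reference
#'   device).
#' @export
transfer_mask <- function(mask, map = overlap_limits()) {
  stopifnot(inherits(mask, "body_mask"))
  if (mask$space != "rgb") stop("transfer_mask expects an RGB-space mask")
  out <- matrix(FALSE, map$ir_height_px, map$ir_width_px)
  idx <- which(mask$grid, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    # matrix row/col are 1-based; pixel equations are 0-based
    p <- rgb_to_depth_pixel(idx[, "col"] - 1, idx[, "row"] - 1, map)
    ci <- round(p$x) + 1L
    ri <- round(p$y) + 1L
    keep <- p$inside & ci >= 1L & ci <= map$ir_width_px &
      ri >= 1L & ri <= map$ir_height_px
    out[cbind(ri[keep], ci[keep])] <- TRUE
  }
  body_mask(out, "depth", mask$timestamp_s)
}

#' Clean a depth-space mask by a depth window
#'
#' Computes the mean range d-bar over masked pixels with valid (> 0) depth
#' and keeps only pixels whose depth lies in the body window
#' `[d-bar - 700, d-bar + 300]` mm; invalid-depth pixels are dropped.
#'
#' @param mask A [body_mask()] in depth space.
#' @param depth A [depth_frame()] of matching dimensions.
#' @param window_mm Length-2 offsets below/above the mean depth defining
#'   the retention window.
#' @return A list: `mask` (cleaned [body_mask()]) and `mean_depth_mm`.
#' @export
clean_mask <- function(mask, depth, window_mm = c(700, 300)) {
  stopifnot(inherits(mask, "body_mask"), inherits(depth, "depth_frame"))
  if (mask$space != "depth") stop("clean_mask expects a depth-space mask")
  if (!all(dim(mask$grid) == dim(depth$grid)))
    stop("mask and depth frame dimensions differ")
  d <- depth$grid[mask$grid]
  d <- d[d > 0]
  if (length(d) == 0) stop("empty mask or no valid depths under the mask")
  dbar <- mean(d)
  keep <- mask$grid & depth$grid > 0 &
    depth$grid >= dbar - window_mm[1] & depth$grid <= dbar + window_mm[2]
  list(mask = body_mask(keep, "depth", mask$timestamp_s), mean_depth_mm = dbar)
}

#' Height factor for the lower-leg cut
#'
#' Experimental factor f giving, as a fraction of the silhouette height,
#' the row limit below which the lower leg lies. Tabulated against the mean
#' body distance (0.5 m: 0.65, 1 m: 0.65, 1.5 m: 0.75, 2 m: 0.8, 3 m: 0.9,
#' 4 m: 0.95); linear interpolation between knots, clamped outside
#' [0.5, 4] m.
#'
#' @param mean_depth_mm Mean body distance in mm (vector allowed).
#' @param table Optional replacement knot table, a data.frame with columns
#'   `distance_m` and `f`.
#' @return Numeric factor(s) in (0, 1).
#' @examples
#' height_factor(1500)  # 0.75
#' @export
height_factor <- function(mean_depth_mm, table = NULL) {
  if (any(mean_depth_mm <= 0)) stop("mean depth must be positive")
  if (is.null(table))
    table <- data.frame(distance_m = c(0.5, 1, 1.5, 2, 3, 4),
                        f = c(0.65, 0.65, 0.75, 0.8, 0.9, 0.95))
  stats::approx(table$distance_m, table$f, xout = mean_depth_mm / 1000,
                method = "linear", rule = 2)$y
}

#' Select the lower-leg region of a cleaned mask
#'
#' Restricts a cleaned body mask to one leg and to the rows below the
#' height limit `lim = f x height`: the silhouette bounding box is
#' computed, the requested horizontal half is retained (`side = "auto"`
#' keeps the largest connected component), and only rows at or below
#' `bbox_top + round(f * bbox_height)` survive, which places the cut below
#' the knee.
#'
#' @param clean A cleaned [body_mask()] in depth space.
#' @param mean_depth_mm Mean body distance from [clean_mask()].
#' @param side `"left"`, `"right"` (halves of the silhouette x-range) or
#'   `"auto"` (largest connected component).
#' @param f Height factor; default looked up from [height_factor()].
#' @return A `leg_region` object: `mask`, `mean_depth_mm`, `lim_row`
#'   (0-based), `side`.
#' @export
select_leg <- function(clean, mean_depth_mm, side = c("auto", "left", "right"),
                       f = height_factor(mean_depth_mm)) {
  side <- match.arg(side)
  stopifnot(inherits(clean, "body_mask"), clean$space == "depth")
  idx <- which(clean$grid, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  g <- clean$grid
  if (side == "auto") {
    lab <- EBImage::bwlabel(g * 1)
    if (max(lab) > 1) {
      counts <- tabulate(lab[lab > 0])
      g <- lab == which.max(counts)
    }
  } else {
    xmid <- (min(idx[, "col"]) + max(idx[, "col"])) / 2
    cols <- seq_len(ncol(g))
    kill <- if (side == "left") cols > xmid else cols < xmid
    g[, kill] <- FALSE
  }
  idx2 <- which(g, arr.ind = TRUE)
  if (nrow(idx2) == 0) stop(sprintf("no pixels on the %s side", side))
  top <- min(idx2[, "row"]); bottom <- max(idx2[, "row"])
  lim_row0 <- (top - 1L) + as.integer(round(f * (bottom - top + 1L)))
  g[seq_len(nrow(g)) - 1L < lim_row0, ] <- FALSE
  if (!any(g)) stop("leg region empty below the height limit")
  structure(list(mask = body_mask(g, "depth", clean$timestamp_s),
                 mean_depth_mm = mean_depth_mm,
                 lim_row = lim_row0, side = side),
            class = "leg_region")
}

#' Extract the projection line across the lower leg
#'
#' Chooses the scan column with the longest run of consecutive masked rows
#' (ties broken toward the region centroid column) and reads the depth
#' profile along it from the bottom-most masked row (foot end) upward.
#' Isolated invalid depths (gaps of at most `max_gap` samples) are filled
#' by linear interpolation from their neighbours; at a longer gap the
#' profile is truncated.
#'
#' @param region A [select_leg()] region.
#' @param depth The matching [depth_frame()].
#' @param min_len Minimum profile length; shorter profiles raise an error.
#' @param max_gap Longest invalid-depth run that is interpolated over.
#' @return A `projection_profile` object in pixel units: `row` (0-based,
#'   strictly decreasing, foot end first), `depth_mm`, `col` (0-based scan
#'   column), `timestamp_s`, `smoothed = FALSE`, `beta_deg = 0`,
#'   `units = "pixel"`.
#' @export
extract_projection_line <- function(region, depth, min_len = 5L, max_gap = 3L) {
  stopifnot(inherits(region, "leg_region"), inherits(depth, "depth_frame"))
  g <- region$mask$grid
  idx <- which(g, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty leg region")
  # longest run of consecutive masked rows per column
  runlen <- vapply(seq_len(ncol(g)), function(j) {
    col <- g[, j]
    if (!any(col)) return(0L)
    r <- rle(col)
    max(r$lengths[r$values])
  }, integer(1))
  best <- max(runlen)
  cand <- which(runlen == best)
  centroid <- mean(idx[, "col"])
  scan_col <- cand[which.min(abs(cand - centroid))]
  rows <- which(g[, scan_col])                  # 1-based, increasing
  rows <- rev(rows)                             # bottom-most (foot) first
  d <- depth$grid[cbind(rows, scan_col)]
  # interpolate isolated invalid returns, truncate at long gaps
  bad <- d <= 0
  if (any(bad)) {
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cut <- length(d) + 1L
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      if (r$lengths[k] > max_gap || starts[k] == 1L || ends[k] == length(d)) {
        cut <- min(cut, starts[k]); next
      }
    }
    if (cut <= length(d)) { d <- d[seq_len(cut - 1L)]; rows <- rows[seq_len(cut - 1L)] }
    bad <- d <= 0
    if (any(bad)) {
      ok <- which(!bad)
      d[bad] <- stats::approx(ok, d[ok], xout = which(bad))$y
    }
  }
  if (length(d) < min_len)
    stop(sprintf("projection line too short: %d < %d samples", length(d), min_len))
  structure(list(row = rows - 1L, depth_mm = d, col = scan_col - 1L,
                 timestamp_s = depth$timestamp_s,
                 smoothed = FALSE, beta_deg = 0, units = "pixel"),
            class = "projection_profile")
}

#' @export
print.projection_profile <- function(x, ...) {
  cat(sprintf("projection_profile [%s]: %d samples%s%s\n", x$units,
              length(x$depth_mm),
              if (isTRUE(x$smoothed)) ", smoothed" else "",
              if (!identical(x$beta_deg, 0)) sprintf(", rotated %.2f deg", x$beta_deg) else ""))
  invisible(x)
}
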