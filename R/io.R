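#' Write and read a depth-frame sequence container
#'
#' A self-describing on-disk layout for depth recordings: a binary payload
#' of consecutive frames (16-bit little-endian unsigned, row-major 424
#' rows x 512 columns, values in mm, 0 = invalid) plus a JSON sidecar
#' (`<path>.json`) holding the per-frame timestamps in seconds. The
#' round-trip is lossless for integer millimetre depths.
#'
#' @param frames List of [depth_frame()]s.
#' @param path Payload path; the sidecar is written next to it.
#' @param width_px,height_px Frame dimensions.
#' @return `write_depth_sequence` returns `path` invisibly;
#'   `read_depth_sequence` returns a list of [depth_frame()]s.
#' @export
write_depth_sequence <- function(frames, path, width_px = 512L, height_px = 424L) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (f in frames) {
    stopifnot(inherits(f, "depth_frame"),
              nrow(f$grid) == height_px, ncol(f$grid) == width_px)
    v <- as.integer(round(t(f$grid)))          # row-major
    v <- ifelse(v > 32767L, v - 65536L, v)     # 16-bit two's complement
    writeBin(v, con, size = 2L, endian = "little")
  }
  ts <- vapply(frames, function(f) f$timestamp_s, numeric(1))
  # full double precision so the round-trip is bit-exact
  writeLines(paste0("[", paste(sprintf("%.17g", ts), collapse = ", "), "]"),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_depth_sequence
#' @export
read_depth_sequence <- function(path, width_px = 512L, height_px = 424L) {
  ts <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frame_bytes <- 2 * width_px * height_px
  sz <- file.info(path)$size
  if (sz != frame_bytes * length(ts))
    stop(sprintf(
      "depth payload size mismatch: %d bytes holds %.2f frames but sidecar lists %d (expected %d bytes)",
      sz, sz / frame_bytes, length(ts), frame_bytes * length(ts)))
  con <- file(path, "rb")
  on.exit(close(con))
  lapply(seq_along(ts), function(i) {
    v <- readBin(con, "integer", n = width_px * height_px, size = 2L,
                 signed = FALSE, endian = "little")
    g <- matrix(as.numeric(v), nrow = height_px, ncol = width_px, byrow = TRUE)
    if (all(g == 0))
      warning(sprintf("frame %d is entirely invalid (all-zero depths)", i))
    depth_frame(g, ts[i])
  })
}

#' Write and read a body mask as 8-bit PNG
#'
#' 0 = background, 255 = body. The image-space tag and timestamp are not
#' stored in the file; supply them on read.
#'
#' @param mask A [body_mask()].
#' @param path PNG path.
#' @param space,timestamp_s Metadata to attach on read.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png` a
#'   [body_mask()].
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "body_mask"))
  png::writePNG(mask$grid * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path, space = c("rgb", "depth"),
                          timestamp_s = NA_real_) {
  space <- match.arg(space)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  body_mask(img > 0.5, space, timestamp_s)
}

#' Write and read an IMU stream as CSV
#'
#' The export format of the reference logging app: header plus columns
#' `epoch_ms` (integer), `elapsed_s`, `pitch_deg`, `roll_deg`, `yaw_deg`;
#' one file per unit. Only `elapsed_s` and `pitch_deg` are consumed.
#'
#' @param s An [imu_stream()].
#' @param path CSV path.
#' @param epoch_origin_ms Epoch of the first sample for the `epoch_ms`
#'   column.
#' @return `write_imu_csv` returns `path` invisibly; `read_imu_csv` an
#'   [imu_stream()].
#' @export
write_imu_csv <- function(s, path, epoch_origin_ms = 0) {
  stopifnot(inherits(s, "imu_stream"))
  df <- data.frame(
    epoch_ms = as.integer(round(epoch_origin_ms + s$timestamps_s * 1000)),
    elapsed_s = s$timestamps_s,
    pitch_deg = s$pitch_deg, roll_deg = 0, yaw_deg = 0)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @param nominal_rate_hz Nominal rate to attach.
#' @export
read_imu_csv <- function(path, nominal_rate_hz = 100) {
  df <- utils::read.csv(path)
  need <- c("elapsed_s", "pitch_deg")
  if (!all(need %in% names(df)))
    stop("IMU CSV must have columns elapsed_s and pitch_deg")
  imu_stream(df$elapsed_s, df$pitch_deg, nominal_rate_hz = nominal_rate_hz)
}

#' Write and read per-frame keypoints as JSON
#'
#' One record per frame: timestamp, named points (knee, ankle, foot) in
#' RGB pixel coordinates, and a source tag (`"kinect_skeleton"`,
#' `"openpose"` or `"synthetic"`).
#'
#' @param keypoints Data.frame as produced by [render_scene()].
#' @param path JSON path.
#' @return `write_keypoints_json` returns `path` invisibly;
#'   `read_keypoints_json` the data.frame.
#' @export
write_keypoints_json <- function(keypoints, path) {
  recs <- lapply(seq_len(nrow(keypoints)), function(i) {
    k <- keypoints[i, ]
    list(timestamp_s = k$timestamp_s,
         knee = c(k$knee_x, k$knee_y),
         ankle = c(k$ankle_x, k$ankle_y),
         foot = c(k$foot_x, k$foot_y),
         source = k$source)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_keypoints_json
#' @export
read_keypoints_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  do.call(rbind, lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    data.frame(frame = i, timestamp_s = r$timestamp_s,
               knee_x = r$knee[[1]], knee_y = r$knee[[2]],
               ankle_x = r$ankle[[1]], ankle_y = r$ankle[[2]],
               foot_x = r$foot[[1]], foot_y = r$foot[[2]],
               source = r$source)
  }))
}

#' Write and read an angle series as CSV
#'
#' Columns `timestamp_s`, `angle_deg`, `sigma_deg`, `method`.
#'
#' @param series An [angle_series()].
#' @param path CSV path.
#' @return `write_angle_series` returns `path` invisibly;
#'   `read_angle_series` an [angle_series()].
#' @export
write_angle_series <- function(series, path) {
  stopifnot(inherits(series, "angle_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_angle_series
#' @export
read_angle_series <- function(path) {
  df <- utils::read.csv(path)
  angle_series(df$timestamp_s, df$angle_deg, df$sigma_deg, df$method)
}

#' Serialize an agreement report to JSON
#'
#' @param report An [agreement_report()].
#' @param path JSON path.
#' @return `path` invisibly.
#' @export
write_agreement_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
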