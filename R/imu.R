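#' IMU Euler-pitch stream
#'
#' Timestamped pitch readings from one inertial measurement unit. Only the
#' pitch Euler angle (rotation about the transverse axis, range
#' [-180, 180] degrees) enters the ankle-angle computation; roll and yaw
#' are carried through unchanged when present.
#'
#' @param timestamps_s Strictly increasing recording timestamps (s).
#' @param pitch_deg Pitch angles (deg), same length.
#' @param nominal_rate_hz Nominal sampling rate of the unit (100 Hz for
#'   the reference hardware).
#' @param corrected Whether the recording clock has been corrected.
#' @return An `imu_stream` object.
#' @export
imu_stream <- function(timestamps_s, pitch_deg, nominal_rate_hz = 100,
                       corrected = FALSE) {
  stopifnot(length(timestamps_s) == length(pitch_deg))
  if (length(timestamps_s) > 1 && any(diff(timestamps_s) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(abs(pitch_deg) > 180)) stop("pitch outside [-180, 180] degrees")
  structure(list(timestamps_s = as.numeric(timestamps_s),
                 pitch_deg = as.numeric(pitch_deg),
                 nominal_rate_hz = nominal_rate_hz,
                 corrected = isTRUE(corrected)),
            class = "imu_stream")
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("imu_stream: %d samples, nominal %g Hz, %s\n",
              length(x$pitch_deg), x$nominal_rate_hz,
              if (x$corrected) "clock-corrected" else "raw clock"))
  invisible(x)
}

#' Correct the IMU recording clock
#'
#' The host computer stores samples at a non-constant rate even though the
#' unit emits them at its nominal frequency, so recorded timestamps are
#' stretched. Matching the area under the real and ideal sample-count
#' curves, N samples must span exactly `(N - 1) / rate` seconds: the
#' recorded timestamps are replaced by a uniform grid at the nominal rate
#' anchored at the first recorded timestamp. Sample values are untouched.
#'
#' @param s An [imu_stream()] with at least 2 samples.
#' @return The stream with uniform timestamps and `corrected = TRUE`.
#' @examples
#' s <- imu_stream(c(0, 0.5, 1.5, 3.0), c(90, 90, 91, 90))
#' correct_clock(s)$timestamps_s  # 0.00 0.01 0.02 0.03
#' @export
correct_clock <- function(s) {
  stopifnot(inherits(s, "imu_stream"))
  if (s$corrected) stop("stream already clock-corrected")
  n <- length(s$timestamps_s)
  if (n < 2) stop("need at least 2 samples to correct the clock")
  s$timestamps_s <- s$timestamps_s[1] + (seq_len(n) - 1) / s$nominal_rate_hz
  s$corrected <- TRUE
  s
}

#' Timestamped angle series
#'
#' The common container for per-frame or per-sample ankle angles produced
#' by any of the methods (projected line, keypoints, IMU), with a
#' per-sample uncertainty (0 for the IMU gold standard, whose intrinsic
#' error is below a tenth of a degree).
#'
#' @param timestamps_s Timestamps (s).
#' @param angle_deg Ankle angles (deg).
#' @param sigma_deg Per-sample uncertainties (deg, `>= 0`).
#' @param method Method tag, e.g. `"projected_line"`, `"three_point"`,
#'   `"imu"`.
#' @return A data.frame of class `angle_series` with those columns.
#' @export
angle_series <- function(timestamps_s, angle_deg, sigma_deg = 0,
                         method = "unknown") {
  stopifnot(length(timestamps_s) == length(angle_deg), all(is.finite(angle_deg)))
  df <- data.frame(timestamp_s = as.numeric(timestamps_s),
                   angle_deg = as.numeric(angle_deg),
                   sigma_deg = rep_len(as.numeric(sigma_deg), length(angle_deg)),
                   method = rep_len(method, length(angle_deg)),
                   stringsAsFactors = FALSE)
  if (any(df$sigma_deg < 0)) stop("sigma_deg must be >= 0")
  class(df) <- c("angle_series", "data.frame")
  df
}

#' IMU ankle angle from leg and foot pitch streams
#'
#' With the leg unit mounted below the knee (pitch alpha, about 90 deg at
#' rest for a vertical shank) and the foot unit on the dorsum (pitch beta,
#' about 0 deg for a flat foot), the ankle angle is
#' `theta = 180 - alpha + beta`, valid for all alpha, beta in [-180, 180].
#' The foot pitch is linearly interpolated onto the leg timestamps
#' restricted to the overlapping time span. The result is reported raw
#' (not wrapped) with `sigma_deg = 0`.
#'
#' @param leg,foot Clock-corrected [imu_stream()]s.
#' @return An [angle_series()] with `method = "imu"`.
#' @export
imu_ankle_angle <- function(leg, foot) {
  stopifnot(inherits(leg, "imu_stream"), inherits(foot, "imu_stream"))
  if (!leg$corrected || !foot$corrected)
    stop("both streams must be clock-corrected first")
  lo <- max(leg$timestamps_s[1], foot$timestamps_s[1])
  hi <- min(leg$timestamps_s[length(leg$timestamps_s)],
            foot$timestamps_s[length(foot$timestamps_s)])
  keep <- leg$timestamps_s >= lo & leg$timestamps_s <= hi
  if (!any(keep)) stop("disjoint time spans")
  t <- leg$timestamps_s[keep]
  beta <- stats::approx(foot$timestamps_s, foot$pitch_deg, xout = t)$y
  theta <- 180 - leg$pitch_deg[keep] + beta
  angle_series(t, theta, sigma_deg = 0, method = "imu")
}

#' Resample an angle series onto target timestamps
#'
#' Linear interpolation onto `target_times`; targets outside the source
#' span are excluded and reported via the `"excluded"` attribute.
#'
#' @param series An [angle_series()].
#' @param target_times Sorted target timestamps (s).
#' @return An [angle_series()] at the retained targets, with attribute
#'   `excluded` holding the out-of-span targets.
#' @export
resample_angles <- function(series, target_times) {
  stopifnot(inherits(series, "angle_series"))
  if (nrow(series) == 0) stop("empty source series")
  if (is.unsorted(target_times)) stop("target times must be sorted")
  lo <- min(series$timestamp_s); hi <- max(series$timestamp_s)
  inside <- target_times >= lo & target_times <= hi
  t <- target_times[inside]
  v <- stats::approx(series$timestamp_s, series$angle_deg, xout = t)$y
  s <- stats::approx(series$timestamp_s, series$sigma_deg, xout = t)$y
  out <- angle_series(t, v, s, method = series$method[1])
  attr(out, "excluded") <- target_times[!inside]
  out
}
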