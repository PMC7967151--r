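#' Pair two angle series by nearest timestamp
#'
#' Pairs each sample of series `a` with the nearest-in-time sample of
#' series `b`, dropping pairs further apart than `max_gap_s`. Devices keep
#' independent clocks, so an optional residual-lag search first shifts `b`
#' over a lag grid (default +/- 2 s at the finer series' median sampling
#' period) and keeps the lag maximizing the Pearson correlation of the
#' paired angles; ties go to the smallest absolute lag.
#'
#' @param a,b [angle_series()] objects with overlapping spans.
#' @param max_gap_s Maximum pairing gap (s).
#' @param align Search for and remove a residual clock lag.
#' @param max_lag_s Half-width of the lag search window (s).
#' @return A `paired_angles` object: data.frame with `time_s`,
#'   `method_a_deg`, `method_b_deg`; attributes `lag_s` (applied to `b`)
#'   and `n`.
#' @export
pair_series <- function(a, b, max_gap_s = 0.05, align = TRUE, max_lag_s = 2) {
  stopifnot(inherits(a, "angle_series"), inherits(b, "angle_series"))
  pair_at <- function(lag) {
    tb <- b$timestamp_s + lag
    j <- findInterval(a$timestamp_s, tb, all.inside = FALSE)
    j0 <- pmax(j, 1L); j1 <- pmin(j + 1L, length(tb))
    d0 <- abs(a$timestamp_s - tb[j0]); d1 <- abs(a$timestamp_s - tb[j1])
    jj <- ifelse(d1 < d0, j1, j0)
    gap <- abs(a$timestamp_s - tb[jj])
    keep <- gap <= max_gap_s
    list(i = which(keep), j = jj[keep])
  }
  lag <- 0
  if (align) {
    step_a <- stats::median(diff(a$timestamp_s))
    step_b <- stats::median(diff(b$timestamp_s))
    step <- min(step_a, step_b, na.rm = TRUE)
    lags <- seq(-max_lag_s, max_lag_s, by = step)
    lags <- lags[order(abs(lags))]  # ties in r resolve to smallest |lag|
    best_r <- -Inf
    for (l in lags) {
      pr <- pair_at(l)
      if (length(pr$i) < 4) next
      xa <- a$angle_deg[pr$i]; xb <- b$angle_deg[pr$j]
      if (stats::sd(xa) < 1e-12 || stats::sd(xb) < 1e-12) {
        r <- if (best_r == -Inf) 0 else -Inf  # constant series: keep first lag
      } else r <- stats::cor(xa, xb)
      if (r > best_r + 1e-12) { best_r <- r; lag <- l }
    }
  }
  pr <- pair_at(lag)
  if (length(pr$i) < 4) stop("fewer than 4 pairs within max_gap_s")
  out <- data.frame(time_s = a$timestamp_s[pr$i],
                    method_a_deg = a$angle_deg[pr$i],
                    method_b_deg = b$angle_deg[pr$j])
  attr(out, "lag_s") <- lag
  attr(out, "n") <- nrow(out)
  class(out) <- c("paired_angles", "data.frame")
  out
}

fisher_ci <- function(r, n, alpha) {
  if (abs(r) >= 1) return(c(r, r))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - alpha / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Correlation coefficients with Fisher-Z confidence intervals
#'
#' Pearson's r for the linear association between the two methods and
#' Spearman's rho (Pearson on mid-ranks) for monotone association, each
#' with a `1 - alpha` confidence interval computed on the Fisher-Z scale,
#' `atanh(r) +/- z_{alpha/2} / sqrt(n - 3)`, and mapped back with `tanh`.
#'
#' @param p A [pair_series()] result (n >= 4, non-constant).
#' @param alpha Significance level (default 0.05 for 95% intervals).
#' @return A list: `pearson_r`, `pearson_lo`, `pearson_hi`,
#'   `spearman_rho`, `spearman_lo`, `spearman_hi`, `n`.
#' @export
correlations <- function(p, alpha = 0.05) {
  stopifnot(inherits(p, "paired_angles"))
  x <- p$method_a_deg; y <- p$method_b_deg
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("correlation undefined for a constant series")
  r <- stats::cor(x, y)
  rho <- stats::cor(rank(x), rank(y))
  ci_r <- fisher_ci(r, n, alpha)
  ci_s <- fisher_ci(rho, n, alpha)
  list(pearson_r = r, pearson_lo = ci_r[1], pearson_hi = ci_r[2],
       spearman_rho = rho, spearman_lo = ci_s[1], spearman_hi = ci_s[2],
       n = n)
}

#' Root-mean-square and mean absolute error between paired methods
#'
#' `RMSE = sqrt(mean((x_a - x_b)^2))` and `MAE = mean(|x_a - x_b|)` over
#' the paired samples, in degrees.
#'
#' @param p A [pair_series()] result.
#' @return Named numeric vector `c(rmse_deg, mae_deg)`.
#' @export
rmse_mae <- function(p) {
  stopifnot(inherits(p, "paired_angles"))
  d <- p$method_a_deg - p$method_b_deg
  c(rmse_deg = sqrt(mean(d^2)), mae_deg = mean(abs(d)))
}

#' Full agreement report between two angle series
#'
#' Convenience wrapper: pairs the two series, then computes correlation
#' coefficients with confidence intervals and the error metrics.
#'
#' @inheritParams pair_series
#' @param alpha Significance level for the intervals.
#' @return An `agreement_report` list combining [correlations()] and
#'   [rmse_mae()] plus the pairing lag and n.
#' @export
agreement_report <- function(a, b, max_gap_s = 0.05, align = TRUE,
                             alpha = 0.05) {
  p <- pair_series(a, b, max_gap_s = max_gap_s, align = align)
  err <- rmse_mae(p)
  cc <- tryCatch(correlations(p, alpha = alpha), error = function(e) {
    warning("correlations undefined (", conditionMessage(e),
            "); reporting errors only", call. = FALSE)
    list(pearson_r = NA_real_, pearson_lo = NA_real_, pearson_hi = NA_real_,
         spearman_rho = NA_real_, spearman_lo = NA_real_,
         spearman_hi = NA_real_, n = nrow(p))
  })
  out <- c(cc,
           list(rmse_deg = unname(err["rmse_deg"]),
                mae_deg = unname(err["mae_deg"]),
                lag_s = attr(p, "lag_s")))
  class(out) <- "agreement_report"
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement over %d pairs (lag %.3f s):\n", x$n, x$lag_s))
  cat(sprintf("  Pearson r  %.3f (%.3f, %.3f)\n", x$pearson_r, x$pearson_lo, x$pearson_hi))
  cat(sprintf("  Spearman   %.3f (%.3f, %.3f)\n", x$spearman_rho, x$spearman_lo, x$spearman_hi))
  cat(sprintf("  RMSE %.2f deg, MAE %.2f deg\n", x$rmse_deg, x$mae_deg))
  invisible(x)
}

#' Depth measurement error model
#'
#' Empirical accuracy model of the time-of-flight sensor:
#' `delta_z = 0.013 * z + 0.0253`, with z and delta_z in metres.
#'
#' @param z_m Depth in metres (`>= 0`, vector allowed).
#' @return Depth standard error in metres.
#' @examples
#' depth_error(2)  # 0.0513 m
#' @export
depth_error <- function(z_m) {
  if (any(z_m < 0)) stop("depth must be >= 0")
  0.013 * z_m + 0.0253
}

angle_from_z <- function(y_knee_mm, y_foot_mm, z_mm) {
  g <- (z_mm^2 + y_knee_mm * y_foot_mm) /
    (sqrt(z_mm^2 + y_knee_mm^2) * sqrt(z_mm^2 + y_foot_mm^2))
  if (any(abs(g) >= 1 - 1e-12)) stop("degenerate geometry: |cos| at 1")
  rad2deg(acos(g))
}

#' Propagated angle uncertainty from the depth error
#'
#' Treating the knee and foot keypoints as sharing the ankle-relative depth
#' offset z (origin at the ankle), the ankle angle is
#' `alpha(z) = arccos g(z)` with
#' `g(z) = (z^2 + y_k y_f) / (sqrt(z^2 + y_k^2) sqrt(z^2 + y_f^2))`.
#' Only the depth error is propagated:
#' `delta_alpha = |d alpha / d z| * delta_z`, with the derivative evaluated
#' by a central difference (relative step 1e-6) and `delta_z` taken from
#' [depth_error()] at the body distance and converted to mm.
#'
#' @param y_knee_mm,y_foot_mm Ankle-relative heights of knee and foot (mm,
#'   both nonzero).
#' @param z_mm Ankle-relative shared depth offset of knee and foot (mm).
#' @param body_z_m Body distance from the camera in metres, at which the
#'   sensor depth error is evaluated; defaults to `z_mm` in metres.
#' @param dz_mm Optional depth error override in mm (bypasses
#'   [depth_error()]).
#' @return `delta_alpha` in degrees (`>= 0`).
#' @export
angle_error <- function(y_knee_mm, y_foot_mm, z_mm, body_z_m = z_mm / 1000,
                        dz_mm = NULL) {
  if (y_knee_mm == 0 || y_foot_mm == 0) stop("y offsets must be nonzero")
  if (z_mm < 0) stop("z must be >= 0")
  if (is.null(dz_mm)) dz_mm <- depth_error(body_z_m) * 1000
  h <- 1e-6 * max(abs(z_mm), 1)
  dfdz <- (angle_from_z(y_knee_mm, y_foot_mm, z_mm + h) -
             angle_from_z(y_knee_mm, y_foot_mm, z_mm - h)) / (2 * h)
  abs(dfdz) * dz_mm
}
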