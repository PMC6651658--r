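# Per-sample orientation estimation from accelerometer + gyroscope, and the
# heading-free orientation stream every downstream feature is built on.

#' Attitude estimator tuning parameters
#'
#' Returns the tuning-parameter set for the adaptive attitude estimator at a
#' given IMU sampling rate. The defaults are rate-specific: window lengths
#' scale with the sampling rate while gains and thresholds stay fixed.
#'
#' @param fs IMU sampling rate in Hz (100 and 40 carry tabulated defaults;
#'   other rates scale the window lengths proportionally).
#' @param sigma_g Gyroscope noise density (rad s^-1); regularizes the
#'   adaptive gain.
#' @param c_a Base accelerometer correction weight (per sample,
#'   dimensionless, 0 < c_a < 1).
#' @param c_m Exponential smoothing constant applied to the adaptive gain
#'   (0 < c_m < 1; larger = smoother).
#' @param n_short,n_long Short / long window lengths (samples) for the
#'   moving variance of the accelerometer magnitude that drives gain
#'   adaptation.
#' @param xi_a Accelerometer gating threshold (m s^-2): samples whose
#'   magnitude deviates from gravity by more are excluded from correction.
#' @param n_m Moving-average window (samples) applied to the accelerometer
#'   before it is used as a gravity reference.
#' @param xi_xy Rate limit on the correction step (normalized units per
#'   second): the tilt correction applied in one sample never exceeds
#'   \code{xi_xy / fs} radians.
#' @return A list of class \code{attitude_params}.
#' @export
attitude_params <- function(fs = 100,
                            sigma_g = 0.01,
                            c_a = 0.1,
                            c_m = 0.99,
                            n_short = NULL,
                            n_long = NULL,
                            xi_a = 1,
                            n_m = NULL,
                            xi_xy = 5) {
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (is.null(n_short)) n_short <- if (fs >= 70) 7L else 3L
  if (is.null(n_long)) n_long <- if (fs >= 70) 49L else 19L
  if (is.null(n_m)) n_m <- if (fs >= 70) 7L else 3L
  stopifnot(c_a > 0, c_a < 1, c_m > 0, c_m < 1,
            n_short >= 1, n_long >= n_short, n_m >= 1, xi_a > 0)
  structure(list(sigma_g = sigma_g, c_a = c_a, c_m = c_m,
                 n_short = as.integer(n_short), n_long = as.integer(n_long),
                 xi_a = xi_a, n_m = as.integer(n_m), xi_xy = xi_xy, fs = fs),
            class = "attitude_params")
}

# Shortest-arc quaternion rotating unit vector a onto unit vector b
# (both expressed in the global frame).
quat_between <- function(a, b) {
  d <- sum(a * b)
  ax <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  n <- sqrt(sum(ax^2))
  if (n < 1e-12) {
    if (d > 0) return(quat_identity())
    # antiparallel: rotate half a turn about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(a[2] * perp[3] - a[3] * perp[2],
            a[3] * perp[1] - a[1] * perp[3],
            a[1] * perp[2] - a[2] * perp[1])
    return(quat_axis_angle(ax, pi))
  }
  quat_axis_angle(ax, atan2(n, d))
}

#' Estimate the sensor orientation from accelerometer and gyroscope streams
#'
#' A complementary/adaptive-gain attitude estimator: the orientation is
#' propagated by strapdown integration of the gyroscope (first-order, step
#' 1/fs) and corrected toward the accelerometer's gravity direction whenever
#' the accelerometer magnitude is within \code{xi_a} of gravity. The
#' correction weight starts from the base gain \code{c_a}, is boosted during
#' quasi-static moments (short-window variance of the accelerometer
#' magnitude small relative to the long-window variance), smoothed by
#' \code{c_m}, and rate-limited to \code{xi_xy / fs} radians per sample.
#' The correction axis is always horizontal, so no yaw is ever injected.
#'
#' Initialization takes the tilt from the first accelerometer sample whose
#' magnitude is within the gate (yaw = 0). By default the estimate is then
#' passed through \code{\link{quat_remove_heading}} sample-by-sample, giving
#' the heading-free orientation stream (yaw identically zero) used by all
#' downstream features.
#'
#' @param imu A data frame with columns \code{t, ax, ay, az} (m s^-2) and
#'   \code{gx, gy, gz} (rad s^-1), sampled at \code{params$fs}.
#' @param params An \code{\link{attitude_params}} object.
#' @param remove_heading Remove yaw from the output (default TRUE).
#' @param g_ref Gravity magnitude (m s^-2).
#' @return A tibble with columns \code{t}, \code{qw, qx, qy, qz} and
#'   \code{heading_degenerate} (TRUE where the device x-axis was too close
#'   to vertical for the heading to be defined and the previous correction
#'   was held).
#' @export
estimate_attitude <- function(imu, params = attitude_params(),
                              remove_heading = TRUE, g_ref = 9.81) {
  acc <- as.matrix(imu[, c("ax", "ay", "az")])
  gyr <- as.matrix(imu[, c("gx", "gy", "gz")])
  if (nrow(acc) != nrow(gyr)) stop("acc and gyr streams differ in length", call. = FALSE)
  n <- nrow(acc)
  fs <- params$fs
  dt <- 1 / fs

  anorm <- sqrt(rowSums(acc^2))
  gate <- abs(anorm - g_ref) <= params$xi_a

  # adaptive gain: boosted when the recent past is quasi-static relative to
  # the longer history, floored/regularized by the gyro noise density
  eps <- params$sigma_g^2
  vshort <- running_variance(anorm, params$n_short)
  vlong <- running_variance(anorm, params$n_long)
  raw_gain <- params$c_a * (vlong + eps) / (vshort + eps)
  raw_gain[is.na(raw_gain)] <- params$c_a
  raw_gain <- pmin(1, raw_gain)

  first <- which(gate)[1]
  if (is.na(first)) first <- 1L  # never quasi-static: start from sample 1 anyway
  ez <- c(0, 0, 1)
  q <- quat_between(acc[first, ] / anorm[first], ez)

  out <- matrix(NA_real_, n, 4)
  max_step <- params$xi_xy / fs
  gain <- params$c_a
  # gravity reference smoothed over n_m samples in the *global* frame:
  # averaging in the rotating sensor frame would bias the direction while
  # the device turns quickly
  gbuf <- matrix(0, params$n_m, 3)
  gcount <- 0L; ghead <- 0L; gsum <- c(0, 0, 0)
  for (k in seq_len(n)) {
    if (k > 1) {
      w <- gyr[k - 1, ]
      wn <- sqrt(sum(w^2))
      if (wn > 0) {
        half <- wn * dt / 2
        dq <- c(cos(half), (w / wn) * sin(half))
        q <- quat_multiply(q, dq)
      }
    }
    gain <- params$c_m * gain + (1 - params$c_m) * raw_gain[k]
    if (gate[k] && k >= first) {
      ga_k <- quat_rotate(q, acc[k, ])
      if (gcount == params$n_m) {
        gsum <- gsum - gbuf[(ghead %% params$n_m) + 1L, ]
      } else {
        gcount <- gcount + 1L
      }
      gbuf[(ghead %% params$n_m) + 1L, ] <- ga_k
      ghead <- ghead + 1L
      gsum <- gsum + ga_k
      ga <- gsum / gcount
      gn <- sqrt(sum(ga^2))
      if (gn > 1e-9) {
        ga <- ga / gn
        err <- acos(max(-1, min(1, ga[3])))
        if (err > 1e-12) {
          ax <- c(ga[2], -ga[1], 0)  # ga x ez, horizontal
          step <- min(gain * err, max_step, err)
          q <- quat_multiply(quat_axis_angle(ax, step), q)
        }
      }
    }
    q <- q / sqrt(sum(q^2))
    out[k, ] <- q
  }

  degen <- rep(FALSE, n)
  if (remove_heading) {
    hf <- quat_remove_heading(out)
    out <- hf$q
    degen <- hf$degenerate
  }
  res <- quat_as_tbl(out)
  res$heading_degenerate <- degen
  if ("t" %in% names(imu)) res <- tibble::add_column(res, t = imu$t, .before = 1)
  res
}
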