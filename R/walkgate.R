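# Walking detection from raw signal energy, on-line learning of the
# device's upright orientation, and the shortest-rotation tilt stream.
#
# The central idea: the body is upright while walking, so the average device
# orientation over detected walking samples defines "upright" for *this*
# mounting of the device. Comparing the recent average orientation against
# that learned reference separates standing from sedentary postures without
# knowing how the device sits in the pocket.

#' Detect walking samples from raw gyroscope and accelerometer energy
#'
#' A sample is flagged as walking when the squared magnitude of the raw
#' gyroscope exceeds \code{thr_gyro} AND the sliding unbiased variance
#' (0.25 s window) of the squared accelerometer magnitude exceeds
#' \code{thr_accvar}. Both quantities are rotation invariant, so the flags
#' are bit-identical under any virtual re-orientation of the device.
#' Warm-up samples (variance undefined) are never flagged.
#'
#' @param imu Data frame with columns \code{ax, ay, az, gx, gy, gz}.
#' @param fs IMU sampling rate (Hz).
#' @param thr_gyro Threshold on the squared gyro magnitude (rad^2 s^-2).
#' @param thr_accvar Threshold on the variance of the squared accelerometer
#'   magnitude (m^4 s^-4).
#' @return Logical vector, one flag per sample.
#' @export
detect_walking <- function(imu, fs, thr_gyro = 5, thr_accvar = 10) {
  gyr2 <- imu$gx^2 + imu$gy^2 + imu$gz^2
  acc2 <- imu$ax^2 + imu$ay^2 + imu$az^2
  win <- max(2L, as.integer(floor(0.25 * fs)))
  v <- running_variance(acc2, win)
  b <- gyr2 > thr_gyro & !is.na(v) & v > thr_accvar
  b
}

#' Learn the upright orientation from walking-period orientations
#'
#' Maintains a FIFO buffer of the most recent \code{floor(2.5 * fs)}
#' heading-free orientations for which the walking flag is set (the indices
#' need not be contiguous) and emits their hemisphere-aligned running mean
#' at every sample. Before the first walking sample the upright orientation
#' is unset (\code{NA} rows). The buffer persists across non-walking gaps
#' indefinitely: the reference only moves when new walking evidence arrives.
#'
#' @param q n-by-4 matrix (or tibble with qw..qz columns) of heading-free
#'   unit quaternions.
#' @param b_walk Logical walking flags, length n.
#' @param fs IMU sampling rate (Hz).
#' @return An n-by-4 matrix of upright-orientation quaternions (rows NA
#'   until the first walking sample).
#' @export
learn_upright <- function(q, b_walk, fs) {
  m <- if (is.data.frame(q)) quat_cols(q) else as_quat_mat(q)
  n <- nrow(m)
  if (length(b_walk) != n) stop("b_walk length must match q", call. = FALSE)
  cap <- max(1L, as.integer(floor(2.5 * fs)))
  out <- matrix(NA_real_, n, 4)
  buf <- matrix(0, cap, 4)
  head <- 0L; count <- 0L
  s <- c(0, 0, 0, 0)
  cur <- NULL
  for (k in seq_len(n)) {
    if (isTRUE(b_walk[k])) {
      qi <- m[k, ]
      if (count > 0L && sum(qi * s) < 0) qi <- -qi
      if (count == cap) {
        s <- s - buf[(head %% cap) + 1L, ]
      } else {
        count <- count + 1L
      }
      buf[(head %% cap) + 1L, ] <- qi
      head <- head + 1L
      s <- s + qi
      nrm <- sqrt(sum(s^2))
      if (nrm < 1e-9) stop("upright average degenerate", call. = FALSE)
      cur <- s / nrm
    }
    if (!is.null(cur)) out[k, ] <- cur
  }
  out
}

#' Shortest-rotation tilt stream
#'
#' The geodesic angle between the learned upright orientation and the
#' smoothed recent orientation, per sample. Near zero while the wearer is
#' upright (standing, walking) and close to pi/2 when sedentary, whatever
#' the device's mounting orientation. \code{NA} (upright unset) propagates.
#'
#' @param q_avg n-by-4 matrix of smoothed (2.5 s moving average)
#'   heading-free orientations.
#' @param q_upright n-by-4 matrix from \code{\link{learn_upright}}.
#' @return Numeric vector of angles in radians, \code{NA} where the upright
#'   orientation is not yet learned.
#' @export
tilt_stream <- function(q_avg, q_upright) {
  a <- if (is.data.frame(q_avg)) quat_cols(q_avg) else as_quat_mat(q_avg)
  # the upright series legitimately carries NA rows before the first
  # walking sample, so skip the finite-ness validation here
  u <- if (is.data.frame(q_upright)) as.matrix(q_upright[, QUAT_COLS]) else {
    if (is.matrix(q_upright)) q_upright else matrix(q_upright, nrow = 1)
  }
  if (nrow(a) != nrow(u)) stop("series lengths differ", call. = FALSE)
  unset <- is.na(u[, 1])
  out <- rep(NA_real_, nrow(a))
  if (any(!unset)) {
    out[!unset] <- quat_angle(u[!unset, , drop = FALSE], a[!unset, , drop = FALSE])
  }
  out
}
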