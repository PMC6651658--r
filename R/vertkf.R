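# Vertical-velocity estimation: gravity removal in the sensor frame,
# inertial acceleration in the global frame, and a two-state (altitude,
# vertical velocity) extended Kalman filter fusing the vertical inertial
# acceleration with barometric pressure.

BARO_SCALE_M <- 44330.77   # barometric formula altitude scale (m)
BARO_EXPONENT <- 5.26

#' Vertical Kalman filter parameters
#'
#' @param sigma_acc Process-noise scale (m s^-2). Should satisfy
#'   \code{a_m / 2 <= sigma_acc <= a_m} where \code{a_m} is the expected
#'   maximum acceleration magnitude; default 5 (mid-range for a_m = 10).
#' @param sigma_bar Barometer noise SD (hPa), ideally measured from a
#'   stationary segment; default 0.05.
#' @param p0 Reference pressure mapped to altitude zero (hPa). \code{NULL}
#'   means: estimate from the first second of barometer data (all altitudes
#'   are relative).
#' @param T IMU sampling interval (s).
#' @param g_ref Gravity magnitude as measured during a quasi-static period
#'   (m s^-2).
#' @return A list of class \code{vertkf_params}.
#' @export
vertkf_params <- function(sigma_acc = 5, sigma_bar = 0.05, p0 = NULL,
                          T = 0.01, g_ref = 9.81) {
  stopifnot(sigma_acc > 0, sigma_bar > 0, T > 0, is.null(p0) || p0 > 0)
  structure(list(sigma_acc = sigma_acc, sigma_bar = sigma_bar, p0 = p0,
                 T = T, g_ref = g_ref),
            class = "vertkf_params")
}

#' Gravity direction and reference in the sensor frame
#'
#' The unit vector of global "up" expressed in the sensor frame is the third
#' row of the sensor-to-global rotation matrix:
#' \code{(2(q1 q3 - q0 q2), 2(q2 q3 + q0 q1), q0^2 - q1^2 - q2^2 + q3^2)}.
#' Scaled by \code{g_ref} it is the accelerometer reading a static sensor
#' at this orientation would produce.
#'
#' @param q Unit quaternion(s) (vector or n-by-4 matrix).
#' @param g_ref Gravity magnitude (m s^-2).
#' @return n-by-3 matrix (or length-3 vector) of sensor-frame gravity.
#' @export
gravity_in_sensor_frame <- function(q, g_ref = 9.81) {
  vec_in <- !is.matrix(q)
  m <- as_quat_mat(q)
  w <- m[, 1]; x <- m[, 2]; y <- m[, 3]; z <- m[, 4]
  sz <- cbind(2 * (x * z - w * y),
              2 * (y * z + w * x),
              w^2 - x^2 - y^2 + z^2, deparse.level = 0)
  drop_if_single(g_ref * sz, vec_in)
}

#' Inertial acceleration in the global frame
#'
#' Subtracts the sensor-frame gravity reference from the raw accelerometer
#' measurement and rotates the remainder into the global frame. For a static
#' sensor whose reading equals true gravity the result is zero.
#'
#' @param acc Raw accelerometer sample(s), length-3 or n-by-3 (m s^-2).
#' @param q Unit quaternion(s), sensor-to-global.
#' @param g_ref Gravity magnitude (m s^-2).
#' @return Global-frame inertial acceleration, same shape as \code{acc}.
#' @export
inertial_acceleration_global <- function(acc, q, g_ref = 9.81) {
  vec_in <- !is.matrix(acc) && !is.matrix(q)
  a <- as_vec3_mat(acc, "acc")
  g <- gravity_in_sensor_frame(q, g_ref)
  if (!is.matrix(g)) g <- matrix(g, 1)
  n <- max(nrow(a), nrow(g))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(g) == 1 && n > 1) g <- g[rep(1, n), , drop = FALSE]
  drop_if_single(quat_rotate(q, a - g), vec_in)
}

#' Altitude-to-pressure observation model and its Jacobian
#'
#' The international barometric formula
#' \code{h(z) = p0 (1 - z / 44330.77)^5.26} (hPa), strictly decreasing in z
#' for the altitudes of interest, and its derivative with respect to z.
#'
#' @param z Altitude (m).
#' @param p0 Reference sea-level pressure (hPa).
#' @return \code{baro_pressure}: pressure in hPa; \code{baro_jacobian}:
#'   dp/dz in hPa per metre.
#' @export
baro_pressure <- function(z, p0) {
  p0 * (1 - z / BARO_SCALE_M)^BARO_EXPONENT
}

#' @rdname baro_pressure
#' @export
baro_jacobian <- function(z, p0) {
  -(BARO_EXPONENT * p0 / BARO_SCALE_M) * (1 - z / BARO_SCALE_M)^(BARO_EXPONENT - 1)
}

#' Invert the barometric formula
#'
#' @rdname baro_pressure
#' @param p Pressure (hPa).
#' @export
baro_altitude <- function(p, p0) {
  BARO_SCALE_M * (1 - (p / p0)^(1 / BARO_EXPONENT))
}

new_vert_state <- function(z = 0, z_dot = 0, P = diag(c(1, 1))) {
  list(x = c(z, z_dot), P = P)
}

#' Kalman prediction step of the vertical filter
#'
#' Constant-acceleration propagation over one IMU sampling interval:
#' \code{x- = A x + G u} with \code{A = [[1, T], [0, 1]]},
#' \code{G = (T^2/2, T)} and process noise \code{Q = G G' sigma_acc^2}.
#'
#' @param state List with \code{x} (z, z_dot) and 2x2 covariance \code{P}.
#' @param u Vertical inertial acceleration input (m s^-2).
#' @param params A \code{\link{vertkf_params}} object.
#' @return The propagated state.
#' @export
kf_predict <- function(state, u, params) {
  T <- params$T
  A <- matrix(c(1, T, 0, 1), 2, 2, byrow = TRUE)
  G <- c(T^2 / 2, T)
  x <- as.numeric(A %*% state$x) + G * u
  Q <- tcrossprod(G) * params$sigma_acc^2
  P <- A %*% state$P %*% t(A) + Q
  P <- (P + t(P)) / 2
  list(x = x, P = P)
}

#' Kalman update step of the vertical filter
#'
#' Extended-Kalman measurement update against a barometric pressure sample:
#' the barometric formula maps predicted altitude to pressure, the scalar
#' innovation is gained into both states, and the covariance contracts.
#'
#' @param state Prior state from \code{\link{kf_predict}}.
#' @param p Measured pressure (hPa), > 0.
#' @param params A \code{\link{vertkf_params}} object with \code{p0} set.
#' @return The posterior state.
#' @export
kf_update <- function(state, p, params) {
  if (!is.finite(p) || p <= 0) stop("pressure must be positive", call. = FALSE)
  z <- state$x[1]
  H <- c(baro_jacobian(z, params$p0), 0)
  S <- as.numeric(H %*% state$P %*% H) + params$sigma_bar^2
  if (S <= 0) stop("non-positive innovation covariance: numerical failure", call. = FALSE)
  K <- as.numeric(state$P %*% H) / S
  resid <- p - baro_pressure(z, params$p0)
  x <- state$x + K * resid
  P <- (diag(2) - K %*% t(H)) %*% state$P
  P <- (P + t(P)) / 2
  list(x = x, P = P)
}

#' Estimate vertical velocity by fusing inertial and barometric data
#'
#' Runs the two-state filter along the IMU clock: a prediction with the
#' vertical global-frame inertial acceleration at every IMU sample, and a
#' measurement update at every barometer sample (applied at the nearest
#' preceding IMU tick; the two clocks need not be commensurate). If the
#' barometer goes silent for more than 2 s the filter keeps predicting and
#' flags those samples as degraded.
#'
#' @param imu Data frame with \code{t, ax, ay, az} (m s^-2).
#' @param q n-by-4 matrix (or tibble with qw..qz) of orientations, one per
#'   IMU sample.
#' @param baro Data frame with \code{t} (s) and \code{p} (hPa).
#' @param params A \code{\link{vertkf_params}} object; \code{p0 = NULL} is
#'   replaced by the mean pressure over the first second of barometer data.
#' @return A tibble with \code{t}, altitude \code{z} (m, relative to p0),
#'   vertical velocity \code{z_dot} (m s^-1) and \code{degraded}.
#' @export
estimate_vertical_velocity <- function(imu, q, baro, params = NULL) {
  qm <- if (is.data.frame(q)) quat_cols(q) else as_quat_mat(q)
  n <- nrow(imu)
  if (nrow(qm) != n) stop("orientation series must match the IMU stream", call. = FALSE)
  if (is.null(params)) {
    dt <- stats::median(diff(imu$t))
    params <- vertkf_params(T = dt)
  }
  if (is.null(params$p0)) {
    head_p <- baro$p[baro$t <= baro$t[1] + 1]
    params$p0 <- mean(head_p)
  }
  acc <- as.matrix(imu[, c("ax", "ay", "az")])
  da <- inertial_acceleration_global(acc, qm, params$g_ref)
  uz <- da[, 3]

  # map each barometer sample onto the latest IMU tick at or before it
  upd <- findInterval(baro$t, imu$t)
  keep <- upd >= 1
  upd_at <- split(which(keep), upd[keep])

  state <- new_vert_state(z = baro_altitude(baro$p[1], params$p0))
  zs <- numeric(n); vs <- numeric(n); degraded <- logical(n)
  last_baro_t <- baro$t[1]
  for (k in seq_len(n)) {
    state <- kf_predict(state, uz[k], params)
    bk <- upd_at[[as.character(k)]]
    if (!is.null(bk)) {
      for (j in bk) {
        state <- kf_update(state, baro$p[j], params)
        last_baro_t <- baro$t[j]
      }
    }
    zs[k] <- state$x[1]
    vs[k] <- state$x[2]
    degraded[k] <- (imu$t[k] - last_baro_t) > 2
  }
  tibble::tibble(t = imu$t, z = zs, z_dot = vs, degraded = degraded)
}
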