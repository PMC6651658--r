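# Virtual re-orientation: generate the data a differently-pocketed device
# would have recorded, by rotating the raw inertial vectors with a fixed
# quaternion. Barometric pressure is a scalar and is never transformed.

#' Virtually re-orient an IMU stream
#'
#' Applies a fixed unit quaternion to every accelerometer and gyroscope
#' sample, producing the stream that would have been recorded had the device
#' been mounted in a different orientation. Timestamps and any extra columns
#' are carried through unchanged; per-sample vector norms are preserved.
#'
#' @param imu A data frame with columns \code{ax, ay, az, gx, gy, gz}
#'   (and typically \code{t}).
#' @param q A unit quaternion (length-4, scalar first).
#' @return A tibble of the same shape with rotated \code{a*} and \code{g*}.
#' @export
reorient_imu <- function(imu, q) {
  q <- as.numeric(q)
  check_quat_finite(q)
  if (abs(sum(q^2) - 1) > 1e-6) {
    stop("re-orientation quaternion must be unit norm", call. = FALSE)
  }
  out <- tibble::as_tibble(imu)
  out[, c("ax", "ay", "az")] <- quat_rotate(q, as.matrix(imu[, c("ax", "ay", "az")]))
  out[, c("gx", "gy", "gz")] <- quat_rotate(q, as.matrix(imu[, c("gx", "gy", "gz")]))
  out
}

#' @rdname reorient_imu
#' @param session A session list as returned by
#'   \code{\link{simulate_session}} or \code{\link{read_session}}; only the
#'   IMU stream is transformed (pressure is orientation invariant).
#' @export
reorient_session <- function(session, q) {
  session$imu <- reorient_imu(session$imu, q)
  session
}

#' Canonical in-pocket orientation set
#'
#' Six unit quaternions representative of common ways a device ends up in a
#' pants pocket: (a) the reference orientation (y-axis along the thigh,
#' x-axis mediolateral), (b) upside-down within the pocket plane (half turn
#' about the device z-axis), (c)/(d) pitched a quarter turn either way
#' about the device x-axis (screen tilted toward/away from the thigh),
#' (e) face-flipped (half turn about x) and (f) laterally flipped (half
#' turn about y). Entry (a) is the identity.
#'
#' Every preset maps the device x-axis onto the mediolateral line (+/- x),
#' where it stays horizontal in both the upright and the seated posture.
#' That is deliberate: the heading-removal construction references the
#' horizontal projection of the device x-axis, which is undefined whenever
#' that axis points near vertical -- as happens, for a thigh-pocket device,
#' with quarter-turn remounts about the device y- or z-axes (x lands along
#' the thigh long axis or the anterior axis, each of which is vertical in
#' one of the two postures). Orientation invariance of the tilt feature
#' genuinely degrades there; see the methods vignette.
#'
#' @return A named list of six unit quaternions, names \code{a}-\code{f}.
#' @export
orientation_presets <- function() {
  list(
    a = quat_identity(),
    b = quat_axis_angle(c(0, 0, 1), pi),
    c = quat_axis_angle(c(1, 0, 0), pi / 2),
    d = quat_axis_angle(c(1, 0, 0), -pi / 2),
    e = quat_axis_angle(c(1, 0, 0), pi),
    f = quat_axis_angle(c(0, 1, 0), pi)
  )
}
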