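# Quaternion algebra for attitude processing.
#
# Conventions, fixed package-wide:
#   * Hamilton product, scalar-first storage (w, x, y, z);
#   * right-handed frames, global z points up;
#   * a quaternion q maps sensor-frame coordinates into the global frame,
#     i.e. g_v = q (0, s_v) q*;
#   * q and -q represent the same rotation, so every angle-valued function
#     must be insensitive to the sign of its arguments.
#
# Series of quaternions are plain numeric matrices with four columns
# (w, x, y, z); a single quaternion is a numeric vector of length four.

QUAT_COLS <- c("qw", "qx", "qy", "qz")

#' Construct a unit quaternion
#'
#' Builds a scalar-first Hamilton quaternion \code{(w, x, y, z)} and
#' normalizes it to unit norm. Components must be finite and the norm must
#' be bounded away from zero.
#'
#' @param w,x,y,z Numeric components (scalar part first).
#' @return A numeric vector of length 4 with unit norm.
#' @examples
#' quat(1, 0, 0, 0)            # identity rotation
#' quat_axis_angle(c(0, 0, 1), pi / 2)  # quarter turn about z
#' @export
quat <- function(w, x = 0, y = 0, z = 0) {
  if (length(w) == 4 && missing(x)) {
    q <- as.numeric(w)
  } else {
    q <- c(w, x, y, z)
  }
  check_quat_finite(q)
  n <- sqrt(sum(q^2))
  if (n < 1e-9) {
    stop("quaternion norm is (near) zero; cannot normalize", call. = FALSE)
  }
  q / n
}

check_quat_finite <- function(q) {
  if (length(q) != 4) {
    stop("a quaternion needs exactly 4 components (w, x, y, z)", call. = FALSE)
  }
  bad <- !is.finite(q)
  if (any(bad)) {
    stop(sprintf("non-finite quaternion component: %s",
                 paste(c("w", "x", "y", "z")[bad], collapse = ", ")),
         call. = FALSE)
  }
  invisible(q)
}

#' @rdname quat
#' @export
quat_identity <- function() c(1, 0, 0, 0)

#' @param axis Numeric length-3 rotation axis (need not be unit).
#' @param angle Rotation angle in radians.
#' @rdname quat
#' @export
quat_axis_angle <- function(axis, angle) {
  if (length(axis) != 3 || any(!is.finite(axis))) {
    stop("axis must be a finite length-3 vector", call. = FALSE)
  }
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis has zero norm", call. = FALSE)
  a <- axis / n
  c(cos(angle / 2), a * sin(angle / 2))
}

# Coerce a quaternion argument (length-4 vector or n x 4 matrix) to a matrix.
as_quat_mat <- function(q, arg = "q") {
  if (is.matrix(q)) {
    if (ncol(q) != 4) stop(sprintf("%s must have 4 columns", arg), call. = FALSE)
    m <- q
  } else {
    if (length(q) != 4) stop(sprintf("%s must have 4 components", arg), call. = FALSE)
    m <- matrix(q, nrow = 1)
  }
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)
    stop(sprintf("non-finite quaternion component '%s' in %s (row %d)",
                 c("w", "x", "y", "z")[bad[1, 2]], arg, bad[1, 1]),
         call. = FALSE)
  }
  m
}

as_vec3_mat <- function(v, arg = "v") {
  if (is.matrix(v)) {
    if (ncol(v) != 3) stop(sprintf("%s must have 3 columns", arg), call. = FALSE)
    m <- v
  } else {
    if (length(v) != 3) stop(sprintf("%s must have 3 components", arg), call. = FALSE)
    m <- matrix(v, nrow = 1)
  }
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)
    stop(sprintf("non-finite component '%s' in %s (row %d)",
                 c("x", "y", "z")[bad[1, 2]], arg, bad[1, 1]),
         call. = FALSE)
  }
  m
}

drop_if_single <- function(m, inputs_were_vectors) {
  if (inputs_were_vectors && nrow(m) == 1) as.numeric(m) else m
}

#' Hamilton product of quaternions
#'
#' Composes two rotations: \code{quat_multiply(q1, q2)} is the rotation that
#' applies \code{q2} first, then \code{q1}. Both arguments may be length-4
#' vectors or n-by-4 matrices (vectorized row-wise; single rows recycle).
#'
#' @param q1,q2 Unit quaternions (vector or matrix form).
#' @return The product, in the same shape as the (widest) input.
#' @export
quat_multiply <- function(q1, q2) {
  vec_in <- !is.matrix(q1) && !is.matrix(q2)
  a <- as_quat_mat(q1, "q1"); b <- as_quat_mat(q2, "q2")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("q1 and q2 must have matching lengths", call. = FALSE)
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  drop_if_single(cbind(w, x, y, z, deparse.level = 0), vec_in)
}

#' @rdname quat_multiply
#' @param q A unit quaternion (vector or matrix form).
#' @export
quat_conjugate <- function(q) {
  vec_in <- !is.matrix(q)
  m <- as_quat_mat(q)
  m[, 2:4] <- -m[, 2:4]
  drop_if_single(m, vec_in)
}

#' Rotate vectors by quaternions
#'
#' Computes the vector part of \code{q (0, v) q*}, mapping sensor-frame
#' coordinates into the global frame under the package convention. Norms are
#' preserved. Vectorized row-wise over n-by-4 / n-by-3 matrices.
#'
#' @param q Unit quaternion(s).
#' @param v Vector(s) to rotate, length 3 or n-by-3.
#' @return Rotated vector(s), same shape as \code{v} (or widened).
#' @export
quat_rotate <- function(q, v) {
  vec_in <- !is.matrix(q) && !is.matrix(v)
  qm <- as_quat_mat(q); vm <- as_vec3_mat(v)
  n <- max(nrow(qm), nrow(vm))
  if (nrow(qm) == 1 && n > 1) qm <- qm[rep(1, n), , drop = FALSE]
  if (nrow(vm) == 1 && n > 1) vm <- vm[rep(1, n), , drop = FALSE]
  if (nrow(qm) != nrow(vm)) stop("q and v must have matching lengths", call. = FALSE)
  w <- qm[, 1]; x <- qm[, 2]; y <- qm[, 3]; z <- qm[, 4]
  vx <- vm[, 1]; vy <- vm[, 2]; vz <- vm[, 3]
  # t = 2 (q_vec x v); v' = v + w t + q_vec x t
  tx <- 2 * (y * vz - z * vy)
  ty <- 2 * (z * vx - x * vz)
  tz <- 2 * (x * vy - y * vx)
  rx <- vx + w * tx + (y * tz - z * ty)
  ry <- vy + w * ty + (z * tx - x * tz)
  rz <- vz + w * tz + (x * ty - y * tx)
  drop_if_single(cbind(rx, ry, rz, deparse.level = 0), vec_in)
}

#' Rotation matrix of a quaternion
#'
#' @param q A single unit quaternion.
#' @return The 3x3 rotation matrix R with \code{R v = quat_rotate(q, v)}.
#' @export
quat_to_matrix <- function(q) {
  q <- as.numeric(as_quat_mat(q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Shortest rotation angle between two orientations
#'
#' The geodesic angle \eqn{\vartheta = 2 \arccos(\min(1, |\langle q_a, q_b
#' \rangle|))} in \eqn{[0, \pi]}. Symmetric in its arguments and insensitive
#' to the sign of either quaternion (the two-fold cover of rotation space).
#' This is the quantity behind the shortest-rotation tilt feature.
#'
#' @param qa,qb Unit quaternions (vector or matrix form, vectorized).
#' @return Angle(s) in radians, in \eqn{[0, \pi]}.
#' @export
quat_angle <- function(qa, qb) {
  a <- as_quat_mat(qa, "qa"); b <- as_quat_mat(qb, "qb")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("qa and qb must have matching lengths", call. = FALSE)
  d <- abs(rowSums(a * b))
  2 * acos(pmin(1, d))
}

#' Yaw / pitch / roll extraction (z-y-x intrinsic)
#'
#' Euler-angle decomposition used by the heading-removal tests: yaw is the
#' rotation about global z, removed by \code{\link{quat_remove_heading}}.
#'
#' @param q Unit quaternion(s).
#' @return A matrix with columns \code{yaw}, \code{pitch}, \code{roll} (radians).
#' @export
quat_to_euler <- function(q) {
  m <- as_quat_mat(q)
  w <- m[, 1]; x <- m[, 2]; y <- m[, 3]; z <- m[, 4]
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2))
  pitch <- asin(pmax(-1, pmin(1, 2 * (w * y - z * x))))
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2))
  cbind(yaw = yaw, pitch = pitch, roll = roll)
}

#' Remove the heading (yaw) component of an orientation
#'
#' Aligns the xy-projection of the device x-axis with the global x-axis
#' \code{ex = (1, 0, 0)}, so the returned orientation has yaw exactly zero
#' while pitch and roll are preserved. The facing direction of the wearer
#' carries no postural information, so it is discarded before orientations
#' are compared.
#'
#' When the device x-axis is near-vertical (xy-projection norm below
#' \code{tol}) the heading is undefined; the previous heading correction is
#' held (identity at stream start) and the sample is flagged, which avoids
#' step discontinuities in the output.
#'
#' @param q Unit quaternion(s), vector or n-by-4 matrix (a time series).
#' @param fallback Heading correction to hold when undefined (default identity;
#'   for a series the hold is carried forward sample-to-sample).
#' @param tol Degeneracy tolerance on the xy-projection norm.
#' @return A list with elements \code{q} (heading-free orientation, same
#'   shape as input), \code{qnorth} (the applied correction) and
#'   \code{degenerate} (logical flags).
#' @export
quat_remove_heading <- function(q, fallback = quat_identity(), tol = 1e-6) {
  vec_in <- !is.matrix(q)
  m <- as_quat_mat(q)
  w <- m[, 1]; x <- m[, 2]; y <- m[, 3]; z <- m[, 4]
  # global-frame image of the device x-axis, projected onto the xy-plane
  ax <- w^2 + x^2 - y^2 - z^2
  ay <- 2 * (x * y + w * z)
  nrm <- sqrt(ax^2 + ay^2)
  degen <- nrm < tol
  safe <- pmax(nrm, tol)
  ct <- pmax(-1, pmin(1, ax / safe))      # cos(theta) toward ex
  theta <- acos(ct)
  # axis = x_xy x ex = (0, 0, -ay); normalized z-component
  sz <- ifelse(abs(ay) < 1e-12, 1, -sign(ay))
  qn <- cbind(cos(theta / 2), 0, 0, sz * sin(theta / 2))
  if (any(degen)) {
    fb <- as.numeric(as_quat_mat(fallback, "fallback"))
    idx <- seq_len(nrow(m))
    last_ok <- cummax(ifelse(degen, 0L, idx))
    qn[degen & last_ok > 0, ] <- qn[last_ok[degen & last_ok > 0], , drop = FALSE]
    no_prior <- degen & last_ok == 0
    if (any(no_prior)) {
      qn[no_prior, ] <- matrix(fb, sum(no_prior), 4, byrow = TRUE)
    }
  }
  out <- quat_multiply(qn, m)
  list(q = drop_if_single(out, vec_in),
       qnorth = drop_if_single(qn, vec_in),
       degenerate = if (vec_in) degen[1] else degen)
}

#' Hemisphere-aligned quaternion mean
#'
#' One-pass average of a set of unit quaternions: each incoming quaternion's
#' sign is flipped so that its dot product with the running sum is
#' non-negative, components are summed, and the result is renormalized. For
#' tightly clustered orientations (the regime of 2.5 s windows) this matches
#' eigenvector-based averaging to first order at a fraction of the cost.
#'
#' @param q An n-by-4 matrix of unit quaternions (rows), n >= 1.
#' @return A single unit quaternion (length-4 vector).
#' @export
quat_mean <- function(q) {
  m <- as_quat_mat(q)
  if (nrow(m) == 0) stop("no samples: cannot average an empty quaternion set",
                         call. = FALSE)
  s <- m[1, ]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      qi <- m[i, ]
      if (sum(qi * s) < 0) qi <- -qi
      s <- s + qi
    }
  }
  n <- sqrt(sum(s^2))
  if (n < 1e-9) {
    stop("quaternion mean has (near) zero norm: antipodal or degenerate set",
         call. = FALSE)
  }
  s / n
}

#' Sliding-window moving average of a quaternion series
#'
#' Streaming version of \code{\link{quat_mean}} over the most recent
#' \code{window} samples: O(1) add-newest / drop-oldest per step, with the
#' hemisphere alignment of each sample frozen at insertion time. During
#' warm-up (fewer than \code{window} samples seen) the average runs over all
#' samples so far.
#'
#' @param q An n-by-4 matrix of unit quaternions.
#' @param window Window length in samples (>= 1).
#' @return An n-by-4 matrix; row k is the mean over samples
#'   \code{max(1, k - window + 1) .. k}.
#' @export
quat_moving_average <- function(q, window) {
  m <- as_quat_mat(q)
  n <- nrow(m)
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  out <- matrix(NA_real_, n, 4)
  buf <- matrix(0, window, 4)   # ring buffer of sign-aligned samples
  head <- 0L; count <- 0L
  s <- c(0, 0, 0, 0)
  for (k in seq_len(n)) {
    qi <- m[k, ]
    if (count > 0L && sum(qi * s) < 0) qi <- -qi
    if (count == window) {
      oldest <- buf[(head %% window) + 1L, ]
      s <- s - oldest
    } else {
      count <- count + 1L
    }
    buf[(head %% window) + 1L, ] <- qi
    head <- head + 1L
    s <- s + qi
    nrm <- sqrt(sum(s^2))
    if (nrm < 1e-9) {
      stop(sprintf("quaternion moving average degenerate at sample %d", k),
           call. = FALSE)
    }
    out[k, ] <- s / nrm
  }
  out
}

# tibble helpers: quaternion series live as columns qw, qx, qy, qz
quat_cols <- function(df) {
  miss <- setdiff(QUAT_COLS, names(df))
  if (length(miss)) {
    stop(sprintf("missing quaternion columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  as.matrix(df[, QUAT_COLS])
}

quat_as_tbl <- function(m) {
  colnames(m) <- QUAT_COLS
  tibble::as_tibble(m)
}
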