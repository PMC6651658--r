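# Gravity removal and the two-state vertical Kalman filter.

test_that("sensor-frame gravity matches the rotation-matrix third row", {
  expect_equal(gravity_in_sensor_frame(quat_identity(), 9.81), c(0, 0, 9.81))
  rx90 <- quat_axis_angle(c(1, 0, 0), pi / 2)
  g_rx <- gravity_in_sensor_frame(rx90, 9.81)
  expect_equal(g_rx, as.numeric(t(quat_to_matrix(rx90)) %*% c(0, 0, 9.81)),
               tolerance = 1e-12)
  set.seed(401)
  q <- random_quats(300)
  sz <- gravity_in_sensor_frame(q, 1)
  worst <- 0
  for (i in seq_len(300)) {
    worst <- max(worst, max(abs(sz[i, ] - t(quat_to_matrix(q[i, ])) %*% c(0, 0, 1))))
  }
  expect_lt(worst, 1e-9)
  expect_lt(max(abs(sqrt(rowSums(sz^2)) - 1)), 1e-9)
})

test_that("inertial acceleration vanishes for a static sensor and round-trips", {
  set.seed(402)
  q <- random_quats(100)
  static_acc <- gravity_in_sensor_frame(q, 9.81)
  da <- inertial_acceleration_global(static_acc, q, 9.81)
  expect_lt(max(abs(da)), 1e-9)
  # a known vertical boost survives the frame round trip
  boost <- gravity_in_sensor_frame(q, 9.81 + 1) # sensor image of (0,0,g+1)
  da2 <- inertial_acceleration_global(boost, q, 9.81)
  expect_equal(da2[, 1], rep(0, 100), tolerance = 1e-9)
  expect_equal(da2[, 3], rep(1, 100), tolerance = 1e-9)
  # arbitrary global vector expressed in the sensor frame comes back intact
  v <- c(0.4, -1.2, 0.7)
  for (i in 1:20) {
    acc_i <- quat_rotate(quat_conjugate(q[i, ]), v) + gravity_in_sensor_frame(q[i, ], 9.81)
    expect_equal(inertial_acceleration_global(acc_i, q[i, ], 9.81), v,
                 tolerance = 1e-9)
  }
})

test_that("the prediction step matches direct matrix arithmetic", {
  pars <- vertkf_params(T = 0.01, p0 = 1000)
  s0 <- list(x = c(0, 0), P = diag(2))
  s1 <- kf_predict(s0, 0, pars)
  expect_equal(s1$x, c(0, 0))
  expect_true(all(s1$P >= diag(2) - 1e-12))  # P grows by Q
  s2 <- kf_predict(list(x = c(0, 1), P = diag(2)), 0, pars)
  expect_equal(s2$x[1], 0.01)
  set.seed(403)
  for (i in 1:100) {
    P <- crossprod(matrix(stats::rnorm(4), 2, 2)) + diag(2) * 0.1
    x <- stats::rnorm(2); u <- stats::rnorm(1)
    out <- kf_predict(list(x = x, P = P), u, pars)
    A <- matrix(c(1, 0.01, 0, 1), 2, 2, byrow = TRUE)
    G <- c(0.01^2 / 2, 0.01)
    expect_equal(out$x, as.numeric(A %*% x + G * u), tolerance = 1e-12)
    expect_equal(out$P, A %*% P %*% t(A) + tcrossprod(G) * pars$sigma_acc^2,
                 tolerance = 1e-12)
    ev <- eigen(out$P, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-12))
  }
})

test_that("the barometric observation model behaves as printed", {
  p0 <- 1013.25
  expect_equal(baro_pressure(0, p0), p0)
  z <- seq(0, 1000, by = 25)
  expect_true(all(diff(baro_pressure(z, p0)) < 0))  # strictly decreasing
  # Jacobian vs central finite differences
  zz <- seq(-100, 1000, by = 50)
  h <- 1e-3
  fd <- (baro_pressure(zz + h, p0) - baro_pressure(zz - h, p0)) / (2 * h)
  expect_lt(max(abs(baro_jacobian(zz, p0) - fd) / abs(fd)), 1e-6)
  # round trip
  expect_equal(baro_altitude(baro_pressure(123.4, p0), p0), 123.4)
})

test_that("the update step leaves a consistent state untouched and contracts P", {
  pars <- vertkf_params(T = 0.01, p0 = 1000, sigma_bar = 0.05)
  s <- list(x = c(0, 0.3), P = diag(c(0.5, 0.5)))
  upd <- kf_update(s, 1000, pars)      # pressure exactly at reference
  expect_equal(upd$x[1], 0, tolerance = 1e-12)
  expect_lte(sum(diag(upd$P)), sum(diag(s$P)) + 1e-12)
  expect_equal(upd$P, t(upd$P))
  expect_error(kf_update(s, -5, pars), "positive")
})

test_that("covariance stays symmetric PSD over many predict/update cycles", {
  pars <- vertkf_params(T = 0.01, p0 = 1000)
  s <- list(x = c(0, 0), P = diag(2))
  set.seed(404)
  for (i in seq_len(20000)) {
    s <- kf_predict(s, stats::rnorm(1), pars)
    if (i %% 6 == 0) s <- kf_update(s, 1000 + stats::rnorm(1, 0, 0.05), pars)
  }
  expect_equal(s$P, t(s$P))
  ev <- eigen(s$P, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-12))
})

test_that("a stationary sensor converges to near-zero vertical velocity", {
  n <- 1000; fs <- 100
  imu <- tibble::tibble(t = (seq_len(n) - 1) / fs, ax = 0, ay = 0, az = 9.81)
  q <- matrix(quat_identity(), n, 4, byrow = TRUE)
  baro <- tibble::tibble(t = seq(0, 9.9, by = 1 / 16), p = 1013.25)
  out <- estimate_vertical_velocity(imu, q, baro,
                                    vertkf_params(T = 1 / fs, p0 = 1013.25))
  expect_lt(max(abs(out$z_dot[imu$t > 5])), 0.05)
  expect_false(any(out$degraded))
})

test_that("stair ascent and descent velocities are recovered within 10%", {
  ss <- stair_session()
  pl <- stair_pipeline()
  lab <- ss$truth$label
  tt <- pl$streams$t
  seg_mean <- function(l) {
    rows <- which(lab == l)
    # steady-state portion: trim 2 s at each segment edge
    lo <- min(tt[rows]) + 2; hi <- max(tt[rows]) - 2
    mean(pl$streams$z_dot[lab == l & tt >= lo & tt <= hi])
  }
  expect_lt(abs(seg_mean("walking_upstairs") - 0.3) / 0.3, 0.1)
  expect_lt(abs(seg_mean("walking_downstairs") + 0.3) / 0.3, 0.1)
})

test_that("an altitude ramp encoded in pressure is recovered via the filter", {
  # pressure generated by inverting the observation model around p0
  n <- 3000; fs <- 100
  slope <- 0.5
  imu <- tibble::tibble(t = (seq_len(n) - 1) / fs, ax = 0, ay = 0, az = 9.81)
  q <- matrix(quat_identity(), n, 4, byrow = TRUE)
  tb <- seq(0, (n - 1) / fs, by = 1 / 16)
  baro <- tibble::tibble(t = tb, p = baro_pressure(slope * tb, 1013.25))
  out <- estimate_vertical_velocity(imu, q, baro,
                                    vertkf_params(T = 1 / fs, p0 = 1013.25))
  est_slope <- mean(out$z_dot[imu$t > 5])
  expect_lt(abs(est_slope - slope) / slope, 0.1)
})

test_that("barometer gaps longer than 2 s are flagged as degraded", {
  n <- 800; fs <- 100
  imu <- tibble::tibble(t = (seq_len(n) - 1) / fs, ax = 0, ay = 0, az = 9.81)
  q <- matrix(quat_identity(), n, 4, byrow = TRUE)
  tb <- c(seq(0, 2, by = 1 / 16), seq(6, 7.9, by = 1 / 16))
  baro <- tibble::tibble(t = tb, p = rep(1013.25, length(tb)))
  out <- estimate_vertical_velocity(imu, q, baro,
                                    vertkf_params(T = 1 / fs, p0 = 1013.25))
  expect_true(any(out$degraded[imu$t > 4 & imu$t < 6]))
  expect_false(any(out$degraded[imu$t > 6.5]))
})

test_that("vertical velocity is invariant to virtual re-orientation", {
  ss <- stair_session()
  base <- stair_pipeline()$streams$z_dot
  rot <- run_pipeline(reorient_session(ss, orientation_presets()$e))
  expect_lt(sqrt(mean((rot$streams$z_dot - base)^2)), 0.05)
})
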