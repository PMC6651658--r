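# Synthetic pocket-IMU sessions with ground truth.
#
# The generator is deliberately minimal biomechanics: a thigh-fixed frame
# whose long axis is vertical when upright and horizontal when sedentary,
# a single-frequency pitch oscillation plus a transverse (yaw) oscillation
# during gait, a small vertical bounce that drives the walking detector's
# variance channel, an effort/impact transient during postural transitions,
# an altitude ramp on stairs with pressure generated by inverting the
# barometric formula, and a fixed (slowly wobbling) mounting quaternion
# between device and thigh. It tests the pipeline's computation, not gait
# realism.

#' Build an activity script
#'
#' @param activity Character vector of activities (see
#'   \code{\link{activity_levels}}; \code{postural_transition} segments are
#'   inserted automatically between standing-like and sedentary neighbours
#'   and normally do not appear here).
#' @param duration Segment durations in seconds (> 0).
#' @return A tibble with columns \code{activity}, \code{duration}.
#' @export
activity_script <- function(activity, duration) {
  activity <- as.character(activity)
  bad <- setdiff(activity, activity_levels())
  if (length(bad)) stop(sprintf("unknown activity: %s", paste(bad, collapse = ", ")),
                        call. = FALSE)
  if (any(!is.finite(duration) | duration <= 0)) {
    stop("durations must be positive and finite", call. = FALSE)
  }
  tibble::tibble(activity = activity, duration = as.numeric(duration))
}

#' Simulation parameters
#'
#' Defaults describe a thigh-pocket device: gait cadence 1.8 Hz with a
#' 0.4 rad thigh-pitch oscillation and a 0.3 rad transverse oscillation a
#' quarter cycle out of phase (so the gyro magnitude never collapses at the
#' pitch extremes), stair climb/descent rate 0.3 m/s, 2 s postural
#' transitions with a 12 m/s^2 damped 5 Hz effort/impact transient and a
#' 0.45 m hip-height change, a ~2 m/s^2 vertical bounce at twice the
#' cadence, and modest sensor noise.
#'
#' @param fs_imu IMU sampling rate (Hz), 100 or 40.
#' @param fs_bar Barometer rate (Hz), 16 or 20.
#' @param mounting_q Device-to-thigh unit quaternion.
#' @param cadence Gait frequency (Hz).
#' @param thigh_pitch_amp Pitch oscillation amplitude (rad).
#' @param walk_yaw_amp Transverse oscillation amplitude (rad).
#' @param walk_bounce_acc Peak vertical bounce acceleration (m s^-2).
#' @param stair_vz Stair vertical speed (m s^-1, magnitude).
#' @param pt_duration Postural-transition duration (s).
#' @param pt_drop Hip-height change between standing and sitting (m).
#' @param pt_impact_amp,pt_impact_freq,pt_impact_dur Effort/impact
#'   transient: peak acceleration (m s^-2), frequency (Hz), duration (s).
#' @param pt_tremor_amp,pt_tremor_freq Corrective pitch tremor during the
#'   transition (rad, Hz): gives transitions their in-band gyroscope
#'   signature while staying below the walking detector's energy gate.
#' @param acc_noise_sd,gyr_noise_sd,gyr_bias,bar_noise_sd Sensor noise and
#'   bias levels (m s^-2, rad s^-1, rad s^-1, hPa).
#' @param pocket_jitter_sd Slow mounting-wobble amplitude (rad).
#' @param p0 Baseline pressure (hPa).
#' @param g Gravity (m s^-2).
#' @param subject_id Carried into session metadata.
#' @param seed RNG seed; the session is a deterministic function of it.
#' @return A list of class \code{sim_params}.
#' @export
sim_params <- function(fs_imu = 100, fs_bar = 16,
                       mounting_q = quat_identity(),
                       cadence = 1.8,
                       thigh_pitch_amp = 0.4,
                       walk_yaw_amp = 0.3,
                       walk_bounce_acc = 2,
                       stair_vz = 0.3,
                       pt_duration = 2,
                       pt_drop = 0.45,
                       pt_impact_amp = 18,
                       pt_impact_freq = 5,
                       pt_impact_dur = 1.2,
                       pt_tremor_amp = 0.04,
                       pt_tremor_freq = 8,
                       acc_noise_sd = 0.05,
                       gyr_noise_sd = 0.01,
                       gyr_bias = 0.005,
                       bar_noise_sd = 0.03,
                       pocket_jitter_sd = 0.02,
                       p0 = 1013.25,
                       g = 9.81,
                       subject_id = "S01",
                       seed = 1) {
  mounting_q <- quat(mounting_q)
  sds <- c(acc_noise_sd, gyr_noise_sd, bar_noise_sd, pocket_jitter_sd)
  if (any(sds < 0) || any(!is.finite(sds))) {
    stop("noise SDs must be finite and non-negative", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_params")
}

# Insert implicit postural transitions between standing-like and sedentary
# neighbours. "Standing-like" = any upright activity.
expand_script <- function(script, pt_duration) {
  upright <- c("standing", "walking", "walking_upstairs", "walking_downstairs")
  acts <- script$activity
  durs <- script$duration
  out_a <- character(0); out_d <- numeric(0)
  for (i in seq_along(acts)) {
    if (i > 1) {
      a_prev <- acts[i - 1]; a_cur <- acts[i]
      crosses <- (a_prev %in% upright && a_cur == "sedentary") ||
        (a_prev == "sedentary" && a_cur %in% upright)
      if (crosses) {
        out_a <- c(out_a, "postural_transition")
        out_d <- c(out_d, pt_duration)
      }
    }
    out_a <- c(out_a, acts[i])
    out_d <- c(out_d, durs[i])
  }
  tibble::tibble(activity = out_a, duration = out_d,
                 t_start = cumsum(c(0, out_d))[seq_along(out_d)],
                 t_end = cumsum(out_d))
}

cosine_ease <- function(u) (1 - cos(pi * pmin(1, pmax(0, u)))) / 2

#' Simulate a labelled pocket-IMU session
#'
#' Generates synchronized accelerometer/gyroscope and barometer streams, an
#' interval label table and per-sample ground truth (sensor orientation,
#' altitude, vertical velocity) for a scripted sequence of activities, with
#' an arbitrary fixed mounting quaternion. Gyroscope output is the exact
#' discrete body rate of the generated orientation sequence (plus bias and
#' noise); accelerometer output is the sensor-frame image of gravity plus
#' the second derivative of the generated displacement (plus noise);
#' pressure is the barometric-formula image of the generated altitude (plus
#' noise). Deterministic given \code{params$seed}.
#'
#' @param script An \code{\link{activity_script}}.
#' @param params A \code{\link{sim_params}} object.
#' @return A list of class \code{har_session}: \code{imu}, \code{baro},
#'   \code{labels}, \code{truth}, \code{meta}.
#' @export
simulate_session <- function(script, params = sim_params()) {
  p <- params
  segs <- expand_script(script, p$pt_duration)
  total <- sum(segs$duration)
  stair_z <- sum(segs$duration[segs$activity == "walking_upstairs"] * p$stair_vz)
  if (stair_z + sum(segs$duration[segs$activity == "walking_downstairs"] * p$stair_vz) > 100) {
    stop("stair segments drive |altitude| beyond 100 m", call. = FALSE)
  }
  fs <- p$fs_imu
  n <- as.integer(round(total * fs))
  t <- (seq_len(n) - 1) / fs
  seg_idx <- findInterval(t, segs$t_start)
  act <- segs$activity[seg_idx]

  with_preserved_seed(p$seed, {
    # --- posture pitch (0 upright, pi/2 sedentary), eased through PTs ---
    posture_of <- function(a) ifelse(a == "sedentary", pi / 2, 0)
    phi <- posture_of(act)
    for (i in which(segs$activity == "postural_transition")) {
      from <- if (i > 1) posture_of(segs$activity[i - 1]) else 0
      to <- if (i < nrow(segs)) posture_of(segs$activity[i + 1]) else pi / 2
      in_seg <- seg_idx == i
      u <- (t[in_seg] - segs$t_start[i]) / segs$duration[i]
      phi[in_seg] <- from + (to - from) * cosine_ease(u)
    }

    # --- gait envelope with 0.3 s edge ramps ---
    gait <- act %in% c("walking", "walking_upstairs", "walking_downstairs")
    env <- numeric(n)
    for (i in which(segs$activity %in% c("walking", "walking_upstairs",
                                         "walking_downstairs"))) {
      in_seg <- seg_idx == i
      d_edge <- pmin(t[in_seg] - segs$t_start[i], segs$t_end[i] - t[in_seg])
      env[in_seg] <- cosine_ease(d_edge / 0.3)
    }

    # corrective-tremor envelope: active during the movement phase of a
    # transition, dying out 0.6 s before its end so that the tremor and the
    # end-of-transition impact transient (the only source of accelerometer
    # variance) are temporally disjoint -- the walking detector's two gates
    # then never fire together during a transition
    pt_env <- numeric(n)
    for (i in which(segs$activity == "postural_transition")) {
      in_seg <- seg_idx == i
      d_edge <- pmin(t[in_seg] - segs$t_start[i],
                     (segs$t_end[i] - 0.6) - t[in_seg])
      pt_env[in_seg] <- cosine_ease(d_edge / 0.3)
    }

    wt <- 2 * pi * p$cadence * t
    pitch <- phi + p$thigh_pitch_amp * sin(wt) * env +
      p$pt_tremor_amp * sin(2 * pi * p$pt_tremor_freq * t) * pt_env
    yaw <- p$walk_yaw_amp * cos(wt) * env

    # --- slow pocket wobble (two incommensurate slow sinusoids per axis) ---
    jitter_angle <- function() {
      f1 <- stats::runif(1, 0.05, 0.15); f2 <- stats::runif(1, 0.1, 0.25)
      ph <- stats::runif(2, 0, 2 * pi)
      p$pocket_jitter_sd * (sin(2 * pi * f1 * t + ph[1]) +
                              sin(2 * pi * f2 * t + ph[2])) / sqrt(2)
    }
    jx <- jitter_angle(); jy <- jitter_angle(); jz <- jitter_angle()

    # --- orientation chain: thigh pose, wobble, mounting ---
    q_stand <- quat_axis_angle(c(1, 0, 0), pi / 2)   # thigh y -> global z
    q_yaw <- cbind(cos(yaw / 2), 0, 0, sin(yaw / 2))
    q_pitch <- cbind(cos(-pitch / 2), sin(-pitch / 2), 0, 0)
    q_thigh <- quat_multiply(quat_multiply(q_yaw, q_pitch),
                             matrix(q_stand, 1))
    jn <- sqrt(jx^2 + jy^2 + jz^2)
    jn_safe <- pmax(jn, 1e-12)
    q_jit <- cbind(cos(jn / 2),
                   jx / jn_safe * sin(jn / 2),
                   jy / jn_safe * sin(jn / 2),
                   jz / jn_safe * sin(jn / 2))
    q_sensor <- quat_multiply(quat_multiply(q_thigh, q_jit),
                              matrix(p$mounting_q, 1))

    # --- displacement: stairs ramp + posture height + gait bounce + PT burst ---
    vz_prof <- numeric(n)
    vz_prof[act == "walking_upstairs"] <- p$stair_vz
    vz_prof[act == "walking_downstairs"] <- -p$stair_vz
    vz_prof <- vz_prof * env
    z_stairs <- cumsum(vz_prof) / fs
    z_post <- -p$pt_drop * phi / (pi / 2)
    w_b <- 2 * pi * 2 * p$cadence
    z_bounce <- (p$walk_bounce_acc / w_b^2) * sin(w_b * t) * env
    z_tot <- z_stairs + z_post + z_bounce

    # effort/impact transient at the end of each transition (seat contact /
    # final weight acceptance), where the postural rotation rate is near
    # zero: the walking detector's two gates (gyro energy, accelerometer
    # variance) therefore never fire together during a transition
    x_burst <- numeric(n)
    amp_d <- p$pt_impact_amp / (2 * pi * p$pt_impact_freq)^2
    for (i in which(segs$activity == "postural_transition")) {
      tc <- segs$t_end[i] - 0.3
      sig <- p$pt_impact_dur / 10
      x_burst <- x_burst + amp_d * sin(2 * pi * p$pt_impact_freq * (t - tc)) *
        exp(-((t - tc) / sig)^2 / 2)
    }

    a_lin <- cbind(second_derivative(x_burst, fs), 0, second_derivative(z_tot, fs))

    # --- sensor signals ---
    f_global <- a_lin
    f_global[, 3] <- f_global[, 3] + p$g      # specific force: gravity reaction + motion
    acc <- quat_rotate(quat_conjugate(q_sensor), f_global)

    # exact discrete body rates of the generated orientation sequence
    gyr <- matrix(0, n, 3)
    if (n >= 2) {
      d <- quat_multiply(quat_conjugate(q_sensor[1:(n - 1), , drop = FALSE]),
                         q_sensor[2:n, , drop = FALSE])
      flip <- d[, 1] < 0
      d[flip, ] <- -d[flip, ]
      vn <- sqrt(rowSums(d[, 2:4, drop = FALSE]^2))
      ang <- 2 * atan2(vn, d[, 1])
      scale <- ifelse(vn > 1e-12, ang / vn * fs, 0)
      gyr[1:(n - 1), ] <- d[, 2:4, drop = FALSE] * scale
      gyr[n, ] <- gyr[n - 1, ]
    }
    bias <- p$gyr_bias * c(1, 1, 1) / sqrt(3)
    gyr <- gyr + matrix(bias, n, 3, byrow = TRUE) +
      matrix(stats::rnorm(3 * n, 0, p$gyr_noise_sd), n, 3)
    acc <- acc + matrix(stats::rnorm(3 * n, 0, p$acc_noise_sd), n, 3)

    # --- barometer ---
    nb <- as.integer(floor(total * p$fs_bar))
    tb <- (seq_len(nb) - 1) / p$fs_bar
    zb <- stats::approx(t, z_tot, xout = tb, rule = 2)$y
    pb <- baro_pressure(zb, p$p0) + stats::rnorm(nb, 0, p$bar_noise_sd)

    imu <- tibble::tibble(t = t,
                          ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                          gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3])
    baro <- tibble::tibble(t = tb, p = pb)
    labels <- tibble::tibble(t_start = segs$t_start, t_end = segs$t_end,
                             label = segs$activity)
    truth <- quat_as_tbl(q_sensor)
    truth <- tibble::add_column(truth, t = t, .before = 1)
    truth$z <- z_tot
    truth$vz <- first_derivative(z_tot, fs)
    truth$label <- act

    structure(list(imu = imu, baro = baro, labels = labels, truth = truth,
                   meta = list(fs_imu = fs, fs_bar = p$fs_bar,
                               subject_id = p$subject_id, seed = p$seed,
                               p0 = p$p0, g = p$g)),
              class = "har_session")
  })
}

#' @export
print.har_session <- function(x, ...) {
  cat(sprintf("pocket-IMU session: %.1f s @ %g Hz IMU / %g Hz barometer (%s)\n",
              nrow(x$imu) / x$meta$fs_imu, x$meta$fs_imu, x$meta$fs_bar,
              x$meta$subject_id))
  acts <- table(x$truth$label)
  for (nm in names(acts)) {
    cat(sprintf("  %-20s %6.1f s\n", nm, acts[[nm]] / x$meta$fs_imu))
  }
  invisible(x)
}
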