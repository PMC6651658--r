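# Windowed feature extraction: eight features per 2.5 s window with 50%
# overlap. Features 1-4 come from FIR-filtered signals (the prior
# fixed-orientation feature set); features 5-8 are the quaternion-derived,
# orientation-robust replacements.
#
#   f1  mean squared band-pass-filtered angular velocity   (rad^2 s^-2)
#   f2  mean inclination angle of the low-passed accel     (rad)
#   f3  mean squared high-pass (dynamic) acceleration      (m^2 s^-4)
#   f4  mean climb-signed differential pressure            (hPa s^-1)
#   f5  mean squared pitch/roll angular velocity (global)  (rad^2 s^-2)
#   f6  mean shortest-rotation tilt vs learned upright     (rad)
#   f7  change in f6 across one full window                (rad)
#   f8  mean Kalman-filtered vertical velocity             (m s^-1)

#' Linear-phase FIR filter bank
#'
#' Designs the three FIR filters used by the classical feature set: a 1-20
#' Hz band-pass per gyroscope axis (gait band), a 0.3 Hz low-pass gravity
#' tracker for the accelerometer, and the implied high-pass dynamic
#' component \code{acc - lowpass(acc)}. All filters are linear phase and are
#' applied with reflection padding and centred convolution, so filtered
#' streams stay time-aligned with the raw streams. The band-pass upper edge
#' is capped at \code{0.45 fs} (at 40 Hz the nominal 20 Hz edge would sit on
#' Nyquist).
#'
#' @param fs Sampling rate (Hz).
#' @return A list with FIR coefficient vectors \code{lp} and \code{bp}.
#' @export
filter_bank <- function(fs) {
  even <- function(k) as.integer(2 * ceiling(k / 2))
  ord_lp <- even(2 * fs)
  ord_bp <- even(fs)
  hi <- min(20, 0.45 * fs)
  lp <- signal::fir1(ord_lp, 0.3 / (fs / 2), type = "low")
  lp <- lp / sum(lp)   # exact unit DC gain: the gravity tracker must not scale
  list(
    lp = lp,
    bp = signal::fir1(ord_bp, c(1, hi) / (fs / 2), type = "pass"),
    fs = fs
  )
}

# Zero-phase FIR application: reflect-pad by half the kernel, centred
# convolution, trim. Output has the same length and alignment as x.
apply_fir <- function(x, h) {
  m <- (length(h) - 1) / 2
  n <- length(x)
  pad_l <- x[pmin(n, m + 1):2]
  pad_r <- x[(n - 1):pmax(1, n - m)]
  xp <- c(pad_l, x, pad_r)
  y <- stats::filter(xp, h, sides = 2)
  as.numeric(y[(m + 1):(m + n)])
}

#' Squared pitch/roll angular-velocity stream
#'
#' Rotates each raw gyroscope sample into the estimated global frame and
#' returns the squared magnitude of its horizontal (x, y) components. The
#' vertical component is excluded: rotation about the global vertical is
#' dominated by turning, which carries no gait information.
#'
#' @param gyr n-by-3 matrix (or data frame with gx, gy, gz) of raw
#'   gyroscope samples (rad s^-1).
#' @param q n-by-4 matrix (or tibble with qw..qz) of heading-free
#'   orientations.
#' @return Numeric vector, one value per sample (rad^2 s^-2).
#' @export
pitch_roll_power <- function(gyr, q) {
  g <- if (is.data.frame(gyr)) as.matrix(gyr[, c("gx", "gy", "gz")]) else as_vec3_mat(gyr)
  qm <- if (is.data.frame(q)) quat_cols(q) else as_quat_mat(q)
  gw <- quat_rotate(qm, g)
  if (!is.matrix(gw)) gw <- matrix(gw, 1)
  gw[, 1]^2 + gw[, 2]^2
}

#' Climb-signed differential pressure
#'
#' Per-sample pressure differential on the barometer clock, sign-flipped so
#' that positive values correspond to ascent (pressure falls as altitude
#' rises). Units hPa s^-1; the first sample is 0.
#'
#' @param p Pressure samples (hPa).
#' @param fs_bar Barometer sampling rate (Hz).
#' @export
differential_pressure <- function(p, fs_bar) {
  c(0, -diff(p)) * fs_bar
}

# zero-order hold of a barometer-clock series onto the IMU clock
hold_to_imu <- function(x_bar, t_bar, t_imu) {
  idx <- findInterval(t_imu, t_bar)
  idx[idx < 1] <- 1
  x_bar[idx]
}

#' Extract the eight-feature table from processed streams
#'
#' Aggregates per-sample streams into 2.5 s windows stepped by 1.25 s (50%
#' overlap), windows starting at the first IMU sample; trailing partial
#' windows are dropped. Windows overlapping the cold-start region (upright
#' orientation not yet learned) carry \code{NA} in f6 and are flagged.
#' f7, the change in f6 across one full window (two steps back), is 0 for
#' the leading windows that have no predecessor.
#'
#' @param imu IMU stream (\code{t, ax..gz}).
#' @param baro Barometer stream (\code{t, p}).
#' @param q Heading-free orientation series (n-by-4 or tibble qw..qz).
#' @param q_avg 2.5 s moving-average orientation series.
#' @param q_upright Learned upright series from \code{\link{learn_upright}}.
#' @param z_dot Vertical-velocity stream (m s^-1), IMU clock.
#' @param fs IMU sampling rate (Hz).
#' @param fs_bar Barometer sampling rate (Hz).
#' @param bank Optional pre-built \code{\link{filter_bank}}.
#' @return A tibble with \code{window_start} (s), \code{f1..f8} and
#'   \code{cold_start}.
#' @export
extract_features <- function(imu, baro, q, q_avg, q_upright, z_dot,
                             fs, fs_bar, bank = NULL) {
  if (is.null(bank)) bank <- filter_bank(fs)
  qm <- if (is.data.frame(q)) quat_cols(q) else as_quat_mat(q)
  n <- nrow(imu)
  N <- as.integer(floor(2.5 * fs))
  step <- N %/% 2L
  if (n < N) stop("stream shorter than one analysis window", call. = FALSE)

  acc <- as.matrix(imu[, c("ax", "ay", "az")])
  gyr <- as.matrix(imu[, c("gx", "gy", "gz")])

  wbpf <- apply(gyr, 2, apply_fir, h = bank$bp)
  wbpf2 <- rowSums(wbpf^2)
  alpf <- apply(acc, 2, apply_fir, h = bank$lp)
  adif <- acc - alpf
  adif2 <- rowSums(adif^2)
  alpf_n <- sqrt(rowSums(alpf^2))
  theta_tilt <- acos(pmax(-1, pmin(1, alpf[, 2] / pmax(alpf_n, 1e-12))))

  dp_bar <- differential_pressure(baro$p, fs_bar)
  dp <- hold_to_imu(dp_bar, baro$t, imu$t)

  gwxy2 <- pitch_roll_power(gyr, qm)
  tilt <- tilt_stream(q_avg, q_upright)

  starts <- seq(1L, n - N + 1L, by = step)
  win_mean <- function(x) {
    vapply(starts, function(s) mean(x[s:(s + N - 1L)]), numeric(1))
  }
  f1 <- win_mean(wbpf2)
  f2 <- win_mean(theta_tilt)
  f3 <- win_mean(adif2)
  f4 <- win_mean(dp)
  f5 <- win_mean(gwxy2)
  f6 <- vapply(starts, function(s) {
    w <- tilt[s:(s + N - 1L)]
    if (anyNA(w)) NA_real_ else mean(w)
  }, numeric(1))
  f8 <- win_mean(z_dot)
  # lag of one full window = two steps at 50% overlap
  f6_lag <- c(NA_real_, NA_real_, f6[seq_len(max(0, length(f6) - 2))])
  f7 <- abs(f6 - f6_lag)
  f7[is.na(f7) & !is.na(f6)] <- 0

  tibble::tibble(
    window_start = imu$t[starts],
    f1 = f1, f2 = f2, f3 = f3, f4 = f4,
    f5 = f5, f6 = f6, f7 = f7, f8 = f8,
    cold_start = is.na(f6)
  )
}

#' Attach majority activity labels to feature windows
#'
#' Each window receives the majority label among its samples, with ties
#' broken toward the label whose annotation interval starts earlier.
#' Windows not covered by any interval are labelled \code{NA} (excluded
#' from training).
#'
#' @param features Feature table from \code{\link{extract_features}}.
#' @param labels Interval annotations: data frame with \code{t_start},
#'   \code{t_end}, \code{label}.
#' @param fs IMU sampling rate (windows span \code{floor(2.5 fs)} samples).
#' @return The feature table with a \code{label} factor column.
#' @export
label_windows <- function(features, labels, fs) {
  N <- as.integer(floor(2.5 * fs))
  labs <- labels[order(labels$t_start), , drop = FALSE]
  lab_of <- function(ts) {
    # per-sample label lookup for the window starting at ts
    tt <- ts + (seq_len(N) - 1) / fs
    i <- findInterval(tt, labs$t_start)
    li <- rep(NA_character_, N)
    ok <- i >= 1
    ok[ok] <- tt[ok] < labs$t_end[i[ok]] + 1e-9
    li[ok] <- labs$label[i[ok]]
    li <- li[!is.na(li)]
    if (!length(li)) return(NA_character_)
    counts <- table(li)
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1) return(top)
    # tie: the label whose interval starts earlier in the window wins
    top[which.min(match(top, li))]
  }
  features$label <- factor(vapply(features$window_start, lab_of, character(1)),
                           levels = activity_levels())
  features
}
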