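# Session files and the end-to-end pipeline.
#
# A session directory holds delimited text:
#   imu.csv    t, ax, ay, az, gx, gy, gz   (s, m s^-2, rad s^-1)
#   baro.csv   t, p                        (s, hPa)
#   labels.csv t_start, t_end, label       (optional)
#   truth.csv  t, qw..qz, z, vz, label     (optional, simulator output)
#   meta.json  fs_imu, fs_bar, subject_id
# IMU and barometer clocks share an epoch.

check_monotone <- function(tv, file) {
  bad <- which(diff(tv) <= 0)
  if (length(bad)) {
    stop(sprintf("%s: timestamps not strictly increasing at row %d",
                 file, bad[1] + 1), call. = FALSE)
  }
}

check_rate <- function(tv, fs, file) {
  if (length(tv) < 2) return(invisible())
  inferred <- 1 / stats::median(diff(tv))
  if (abs(inferred - fs) / fs > 0.01) {
    stop(sprintf("%s: sampling rate inferred from timestamps (%.2f Hz) disagrees with metadata (%g Hz)",
                 file, inferred, fs), call. = FALSE)
  }
}

#' Write / read a session directory
#'
#' Serializes a session (as produced by \code{\link{simulate_session}}) to
#' plain CSV + JSON, and reads it back with validation: timestamps must be
#' strictly increasing and the sampling rate inferred from the median
#' timestamp spacing must agree with the metadata within 1%.
#'
#' @param session A \code{har_session} list.
#' @param dir Directory path (created if needed).
#' @return \code{read_session}: a validated \code{har_session}.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(session$imu, file.path(dir, "imu.csv"), row.names = FALSE)
  utils::write.csv(session$baro, file.path(dir, "baro.csv"), row.names = FALSE)
  if (!is.null(session$labels)) {
    utils::write.csv(session$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  }
  if (!is.null(session$truth)) {
    utils::write.csv(session$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  jsonlite::write_json(session$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  need <- c("imu.csv", "baro.csv", "meta.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop(sprintf("session directory %s is missing: %s", dir,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  imu <- tibble::as_tibble(utils::read.csv(file.path(dir, "imu.csv")))
  baro <- tibble::as_tibble(utils::read.csv(file.path(dir, "baro.csv")))
  imu_cols <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(imu_cols %in% names(imu))) {
    stop("imu.csv: header must contain t, ax, ay, az, gx, gy, gz", call. = FALSE)
  }
  if (!all(c("t", "p") %in% names(baro))) {
    stop("baro.csv: header must contain t, p", call. = FALSE)
  }
  check_monotone(imu$t, "imu.csv")
  check_monotone(baro$t, "baro.csv")
  check_rate(imu$t, meta$fs_imu, "imu.csv")
  check_rate(baro$t, meta$fs_bar, "baro.csv")
  labels <- NULL
  lf <- file.path(dir, "labels.csv")
  if (file.exists(lf)) labels <- tibble::as_tibble(utils::read.csv(lf))
  truth <- NULL
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) truth <- tibble::as_tibble(utils::read.csv(tf))
  structure(list(imu = imu, baro = baro, labels = labels, truth = truth,
                 meta = meta),
            class = "har_session")
}

#' Run the full recognition pipeline on a session
#'
#' Orchestrates every stage in order: attitude estimation and heading
#' removal, orientation smoothing, walking detection and upright learning,
#' vertical-velocity fusion, windowed feature extraction, window labelling
#' (when annotations are present), classification (when a model is given)
#' and scoring (when both are present).
#'
#' @param session A \code{har_session}.
#' @param model Optional fitted \code{\link{hmha}} model.
#' @param g_ref Gravity magnitude (m s^-2).
#' @param verbose Emit per-stage progress messages.
#' @return A list of class \code{har_pipeline}: \code{features} (labelled
#'   when possible, with predictions when a model is given), per-sample
#'   \code{streams} (orientation, walking flags, tilt, vertical velocity)
#'   and, when truth labels and a model are available, a \code{report}
#'   (\code{\link{score}}).
#' @export
run_pipeline <- function(session, model = NULL, g_ref = 9.81, verbose = FALSE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  fs <- session$meta$fs_imu
  fs_bar <- session$meta$fs_bar
  imu <- session$imu
  n <- nrow(imu)

  t0 <- proc.time()[["elapsed"]]
  ap <- attitude_params(fs)
  att <- estimate_attitude(imu, ap, remove_heading = TRUE, g_ref = g_ref)
  qm <- quat_cols(att)
  say("attitude: %d samples @ %g Hz (%.1f s)", n, fs, proc.time()[["elapsed"]] - t0)

  N <- as.integer(floor(2.5 * fs))
  q_avg <- quat_moving_average(qm, N)
  b_walk <- detect_walking(imu, fs)
  q_up <- learn_upright(qm, b_walk, fs)
  tilt <- tilt_stream(q_avg, q_up)
  say("walk gate: %.1f%% of samples flagged walking", 100 * mean(b_walk))
  if (all(!b_walk)) say("no walking detected: tilt features stay unset (cold start)")

  vp <- vertkf_params(T = 1 / fs, g_ref = g_ref)
  vert <- estimate_vertical_velocity(imu, qm, session$baro, vp)

  feats <- extract_features(imu, session$baro, qm, q_avg, q_up, vert$z_dot,
                            fs, fs_bar)
  if (any(feats$cold_start)) {
    say("%d window(s) precede the first learned upright orientation",
        sum(feats$cold_start))
  }
  if (!is.null(session$labels)) {
    feats <- label_windows(feats, session$labels, fs)
  }
  report <- NULL
  if (!is.null(model)) {
    feats <- classify_windows(model, feats)
    if (!is.null(feats$label)) {
      keep <- !is.na(feats$label)
      report <- score(feats$label[keep], feats$.pred[keep])
      say("scored %d windows: kappa %.3f", sum(keep), report$kappa)
    }
  }
  say("features: %d windows", nrow(feats))
  structure(list(
    features = feats,
    streams = tibble::tibble(t = imu$t,
                             qw = qm[, 1], qx = qm[, 2], qy = qm[, 3], qz = qm[, 4],
                             b_walk = b_walk, tilt = tilt,
                             z = vert$z, z_dot = vert$z_dot),
    report = report,
    fs = fs
  ), class = "har_pipeline")
}

#' Feature table of a session
#'
#' Convenience wrapper: runs the pipeline without a classifier and returns
#' the (labelled, when annotations exist) feature table.
#'
#' @inheritParams run_pipeline
#' @export
session_features <- function(session, g_ref = 9.81, verbose = FALSE) {
  run_pipeline(session, model = NULL, g_ref = g_ref, verbose = verbose)$features
}
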