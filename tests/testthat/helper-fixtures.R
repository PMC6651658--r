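# Shared fixtures, built lazily once per test run. Sessions are generated
# in code (no stored data); the cache avoids re-running the attitude /
# Kalman stages for every test file.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, builder(), envir = .fx)
  }
  get(name, envir = .fx, inherits = FALSE)
}

noise_free_params <- function(...) {
  sim_params(acc_noise_sd = 0, gyr_noise_sd = 0, gyr_bias = 0,
             bar_noise_sd = 0, pocket_jitter_sd = 0, ...)
}

# the standard six-class script used for classification fixtures
std_script <- function() {
  activity_script(
    c("walking", "standing", "sedentary", "standing",
      "walking_upstairs", "walking_downstairs"),
    c(20, 10, 10, 6, 20, 20)
  )
}

std_session <- function() {
  fx("std_session", function() simulate_session(std_script(), sim_params(seed = 3)))
}

std_features <- function() {
  fx("std_features", function() session_features(std_session()))
}

std_model <- function(config = "best") {
  key <- paste0("std_model_", config)
  fx(key, function() {
    f <- std_features()
    hmha(f[!is.na(f$label), ], config = config, fs = 100)
  })
}

# feature tables of the standard session under each orientation preset
preset_features <- function() {
  fx("preset_features", function() {
    lapply(orientation_presets(), function(q) {
      session_features(reorient_session(std_session(), q))
    })
  })
}

# stair-heavy session for the vertical filter
stair_session <- function() {
  fx("stair_session", function() {
    sc <- activity_script(
      c("standing", "walking_upstairs", "walking", "walking_downstairs", "standing"),
      c(10, 25, 10, 25, 10)
    )
    simulate_session(sc, sim_params(seed = 5))
  })
}

stair_pipeline <- function() {
  fx("stair_pipeline", function() run_pipeline(stair_session()))
}

# random unit quaternions, n x 4
random_quats <- function(n) {
  m <- matrix(stats::rnorm(4 * n), n, 4)
  m / sqrt(rowSums(m^2))
}

# mean relative RMS difference between two feature columns
rel_rms <- function(a, b) {
  sqrt(mean((a - b)^2)) / max(sqrt(mean(a^2)), 1e-12)
}

# sign-insensitive component-wise distance between quaternions (rows)
quat_dist <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, 1)
  if (!is.matrix(b)) b <- matrix(b, 1)
  pmin(apply(abs(a - b), 1, max), apply(abs(a + b), 1, max))
}

# the t1 protocol: noise-free stand->sit session with a walking bout first,
# mounted with the measurement (y) axis along the thigh long axis
tilt_change_session <- function(mounting_q) {
  sc <- activity_script(c("walking", "standing", "sedentary"), c(8, 10, 10))
  simulate_session(sc, noise_free_params(seed = 11, mounting_q = mounting_q))
}

tilt_change_deg <- function(mounting_q) {
  ss <- tilt_change_session(mounting_q)
  pl <- run_pipeline(ss)
  lab <- ss$truth$label
  med <- function(l) stats::median(pl$streams$tilt[lab == l], na.rm = TRUE)
  abs(med("sedentary") - med("standing")) * 180 / pi
}

# cross-session kappa of a best-config model at a given sampling rate,
# tested on a remounted held-out session (the re-orientation protocol)
rate_kappa <- function(fs_imu, fs_bar) {
  key <- sprintf("rate_kappa_%d", fs_imu)
  fx(key, function() {
    tr <- simulate_session(std_script(),
                           sim_params(fs_imu = fs_imu, fs_bar = fs_bar, seed = 3))
    te <- simulate_session(std_script(),
                           sim_params(fs_imu = fs_imu, fs_bar = fs_bar, seed = 77,
                                      subject_id = "S02"))
    f_tr <- session_features(tr)
    m <- hmha(f_tr[!is.na(f_tr$label), ], config = "best", fs = fs_imu)
    te_rot <- reorient_session(te, orientation_presets()$e)
    cw <- classify_windows(m, session_features(te_rot))
    keep <- !is.na(cw$label)
    score(cw$label[keep], cw$.pred[keep])$kappa
  })
}
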