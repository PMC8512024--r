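# Synthetic seated-posture IMU generator.
#
# Emulates a smartphone strapped at the upper back (T2 vertebra): device
# x-axis points to the subject's right, y up along the spine, z out of the
# back.  A static posture is a fixed trunk orientation, parameterized by a
# pitch (forward flexion, degrees, + = forward) and a roll (lateral lean,
# degrees, + = right).  The accelerometer senses the gravity reaction vector
# rotated into the device frame, the magnetometer the Earth field rotated the
# same way, and the gyroscope the time-derivative of a slow orientation
# wander superimposed on the static angles.

#' Posture models for the five sitting behaviors
#'
#' Builds the per-activity orientation and noise table used by
#' [generate_recording()]. The upright posture `A5` is the zero-rotation
#' reference; left/right leans differ only in the sign of the roll angle and
#' front/back leans only in the sign (and magnitude) of the pitch angle.
#'
#' @param roll_lr Magnitude of the lateral lean for `A1`/`A2`, degrees.
#' @param pitch_front Forward flexion angle for `A3`, degrees (positive).
#' @param pitch_back Backward flexion angle for `A4`, degrees (negative).
#' @param tremor_sd_accel Gaussian tremor SD on the accelerometer, m/s^2.
#' @param tremor_sd_gyro Gaussian tremor SD on the gyroscope, rad/s.
#' @param mag_noise_sd Gaussian noise SD on the magnetometer, microtesla.
#'
#' @return A tibble with one row per activity: `activity`, `pitch`, `roll`,
#'   `tremor_sd_accel`, `tremor_sd_gyro`, `mag_noise_sd`.
#' @export
#' @examples
#' posture_models()
posture_models <- function(roll_lr = 20, pitch_front = 20, pitch_back = -15,
                           tremor_sd_accel = 0.05, tremor_sd_gyro = 0.01,
                           mag_noise_sd = 0.5) {
  stopifnot(tremor_sd_accel > 0, tremor_sd_gyro > 0, mag_noise_sd > 0)
  tibble(
    activity = activity_levels(),
    pitch = c(0, 0, pitch_front, pitch_back, 0),
    roll = c(-roll_lr, roll_lr, 0, 0, 0),
    tremor_sd_accel = tremor_sd_accel,
    tremor_sd_gyro = tremor_sd_gyro,
    mag_noise_sd = mag_noise_sd
  )
}

#' Orientation angles of a posture
#'
#' @param activity One of `"A1"`..`"A5"`.
#' @param postures Posture table from [posture_models()].
#'
#' @return Named numeric vector `c(pitch = , roll = )` in degrees.
#' @export
#' @examples
#' posture_orientation("A5") # c(pitch = 0, roll = 0)
posture_orientation <- function(activity, postures = posture_models()) {
  row <- postures[postures$activity == activity, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown activity id: ", activity),
      class = "sitsense_bad_activity"
    )
  }
  c(pitch = row$pitch, roll = row$roll)
}

#' Simulation configuration
#'
#' Study-condition defaults: 50 Hz sampling, per-activity durations of
#' 712/756/665/590/549 s (the published per-activity recording times), six
#' subjects. `duration_scale` shrinks all durations proportionally for
#' smaller demonstration runs without changing the activity mix.
#'
#' @param sample_rate_hz Sampling rate, Hz.
#' @param durations_s Named vector of per-activity durations, seconds.
#' @param subject_count Number of subjects to simulate.
#' @param seed Root seed; every stream is derived from it deterministically.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param earth_field Earth magnetic field in the neutral device frame, uT.
#' @param drift_amp_deg Stationary SD of the AR(1) orientation wander, degrees
#'   (0 disables drift, making the gyroscope exactly zero-mean noise).
#' @param drift_tau_s Time constant of the orientation wander, seconds.
#' @param subject_angle_sd Per-subject random offset SD on posture angles,
#'   degrees (emulates inter-subject heterogeneity).
#' @param duration_scale Multiplier applied to all durations.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sample_rate_hz = 50,
                       durations_s = c(A1 = 712, A2 = 756, A3 = 665, A4 = 590, A5 = 549),
                       subject_count = 6, seed = 1, gravity = 9.81,
                       earth_field = c(22, 41, -15),
                       drift_amp_deg = 0.5, drift_tau_s = 10,
                       subject_angle_sd = 2, duration_scale = 1) {
  stopifnot(
    sample_rate_hz > 0, subject_count >= 1, duration_scale > 0,
    length(earth_field) == 3
  )
  durations_s <- durations_s * duration_scale
  if (!all(names(durations_s) == activity_levels())) {
    abort("durations_s must be named A1..A5 in order",
      class = "sitsense_bad_config"
    )
  }
  if (any(durations_s < 1)) {
    abort("every activity duration must be at least 1 s",
      class = "sitsense_bad_config"
    )
  }
  structure(
    list(
      sample_rate_hz = sample_rate_hz, durations_s = durations_s,
      subject_count = subject_count, seed = seed, gravity = gravity,
      earth_field = earth_field, drift_amp_deg = drift_amp_deg,
      drift_tau_s = drift_tau_s, subject_angle_sd = subject_angle_sd
    ),
    class = "sim_config"
  )
}

# Intrinsic pitch-then-roll device rotation: R = Rx(pitch) %*% Rz(roll).
# A vector fixed in the neutral frame is sensed in the device frame as
# t(R) %*% v.
rotation_matrix <- function(pitch_deg, roll_deg) {
  p <- pitch_deg * pi / 180
  r <- roll_deg * pi / 180
  rx <- matrix(c(
    1, 0, 0,
    0, cos(p), -sin(p),
    0, sin(p), cos(p)
  ), 3, 3, byrow = TRUE)
  rz <- matrix(c(
    cos(r), -sin(r), 0,
    sin(r), cos(r), 0,
    0, 0, 1
  ), 3, 3, byrow = TRUE)
  rx %*% rz
}

# Sense a neutral-frame vector in the device frame at the given orientation.
# Vectorized over equal-length pitch/roll: returns an n x 3 matrix equal to
# t(R(pitch_i, roll_i)) %*% v row by row.
sense_vector <- function(v, pitch_deg, roll_deg) {
  p <- pitch_deg * pi / 180
  r <- roll_deg * pi / 180
  # u = t(Rx) v ; w = t(Rz) u
  u1 <- rep_len(v[1], length(p))
  u2 <- cos(p) * v[2] + sin(p) * v[3]
  u3 <- -sin(p) * v[2] + cos(p) * v[3]
  cbind(
    cos(r) * u1 + sin(r) * u2,
    -sin(r) * u1 + cos(r) * u2,
    u3,
    deparse.level = 0
  )
}

# Stationary AR(1) wander: sd `amp`, autocorrelation exp(-dt/tau).
ar1_wander <- function(n, amp, tau_s, dt) {
  if (amp <= 0) {
    return(numeric(n))
  }
  phi <- exp(-dt / tau_s)
  innov_sd <- amp * sqrt(1 - phi^2)
  x <- numeric(n)
  eps <- rnorm(n, 0, innov_sd)
  x[1] <- rnorm(1, 0, amp)
  for (i in seq_len(n)[-1]) x[i] <- phi * x[i - 1] + eps[i]
  x
}

#' Generate one subject's labelled 9-channel recording
#'
#' Emits the five activities in order `A1..A5`, each for its configured
#' duration. Within a segment the accelerometer reads the gravity reaction
#' rotated by the posture's (pitch, roll) plus tremor noise; a slow AR(1)
#' orientation wander adds drift, and the gyroscope reads its time
#' derivative (rad/s) plus noise; the magnetometer reads the rotated Earth
#' field plus noise. Identical `(config, subject_id)` gives bitwise-identical
#' output.
#'
#' @param config A [sim_config()].
#' @param postures A [posture_models()] table.
#' @param subject_id Integer subject identifier (>= 1).
#'
#' @return Tibble with columns `time_s`, `ax`,`ay`,`az` (m/s^2),
#'   `gx`,`gy`,`gz` (rad/s), `mx`,`my`,`mz` (uT), `label`, `subject`, and a
#'   `sample_rate_hz` attribute.
#' @export
#' @examples
#' cfg <- sim_config(durations_s = c(A1 = 4, A2 = 4, A3 = 4, A4 = 4, A5 = 4))
#' rec <- generate_recording(cfg, posture_models(), 1)
#' dplyr::count(rec, label)
generate_recording <- function(config, postures, subject_id = 1) {
  stopifnot(inherits(config, "sim_config"), subject_id >= 1)
  if (!setequal(postures$activity, activity_levels())) {
    abort("need exactly one posture model per activity",
      class = "sitsense_bad_config"
    )
  }
  fs <- config$sample_rate_hz
  dt <- 1 / fs

  set.seed(stage_seed(config$seed, paste0("subject-offsets-", subject_id)))
  angle_off <- rnorm(2, 0, config$subject_angle_sd)

  seg_n <- round(config$durations_s * fs)
  if (any(seg_n < 2 * fs)) {
    warn("an activity segment is shorter than 2 s; downstream windowing may be empty")
  }

  set.seed(stage_seed(config$seed, paste0("recording-", subject_id)))
  segs <- lapply(activity_levels(), function(act) {
    pm <- postures[postures$activity == act, ]
    n <- seg_n[[act]]
    pitch <- pm$pitch + angle_off[1] + ar1_wander(n, config$drift_amp_deg, config$drift_tau_s, dt)
    roll <- pm$roll + angle_off[2] + ar1_wander(n, config$drift_amp_deg, config$drift_tau_s, dt)

    g0 <- c(0, config$gravity, 0)
    acc <- sense_vector(g0, pitch, roll)
    mag <- sense_vector(config$earth_field, pitch, roll)
    acc <- acc + matrix(rnorm(3 * n, 0, pm$tremor_sd_accel), n, 3)
    mag <- mag + matrix(rnorm(3 * n, 0, pm$mag_noise_sd), n, 3)

    # angular rates from the wander, deg -> rad; pitch about x, roll about z
    dp <- c(0, diff(pitch)) / dt * pi / 180
    dr <- c(0, diff(roll)) / dt * pi / 180
    gyr <- cbind(dp, 0, dr) + matrix(rnorm(3 * n, 0, pm$tremor_sd_gyro), n, 3)

    tibble(
      ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
      gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3],
      mx = mag[, 1], my = mag[, 2], mz = mag[, 3],
      label = act
    )
  })
  rec <- bind_rows(segs)
  rec <- tibble(
    time_s = (seq_len(nrow(rec)) - 1) / fs, rec,
    subject = as.integer(subject_id)
  )
  attr(rec, "sample_rate_hz") <- fs
  rec
}

#' Simulate the full multi-subject dataset
#'
#' One recording per subject, bound into a single tibble.
#'
#' @inheritParams generate_recording
#' @return Tibble as in [generate_recording()], all subjects stacked.
#' @export
simulate_dataset <- function(config, postures = posture_models()) {
  recs <- lapply(seq_len(config$subject_count), function(s) {
    generate_recording(config, postures, s)
  })
  out <- bind_rows(recs)
  attr(out, "sample_rate_hz") <- config$sample_rate_hz
  out
}

imu_csv_cols <- c(
  "time_s", "ax", "ay", "az", "gx", "gy", "gz",
  "mx", "my", "mz", "label", "subject"
)

#' Read / write the sensor-logger CSV dialect
#'
#' Plain UTF-8 CSV with header
#' `time_s,ax,ay,az,gx,gy,gz,mx,my,mz,label,subject`, one row per sample,
#' `.` decimal separator.
#'
#' @param recording Recording tibble (see [generate_recording()]).
#' @param path File path.
#' @param sample_rate_hz Sampling rate to attach on read; if `NULL`, inferred
#'   from the median time step.
#' @return `write_imu_csv()` returns `path` invisibly; `read_imu_csv()`
#'   returns the recording tibble.
#' @export
write_imu_csv <- function(recording, path) {
  stopifnot(all(imu_csv_cols %in% names(recording)))
  readr::write_csv(recording[imu_csv_cols], path)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path, sample_rate_hz = NULL) {
  rec <- readr::read_csv(
    path,
    col_types = readr::cols(
      label = readr::col_character(),
      subject = readr::col_integer(),
      .default = readr::col_double()
    )
  )
  if (!identical(names(rec), imu_csv_cols)) {
    abort("not a sensor-logger CSV (unexpected header)",
      class = "sitsense_bad_csv"
    )
  }
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- 1 / median(diff(rec$time_s[rec$subject == rec$subject[1]]))
  }
  attr(rec, "sample_rate_hz") <- sample_rate_hz
  rec
}
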