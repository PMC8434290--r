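#' Virtual IMU trace
#'
#' Six-channel time series for one sensor: 3-axis angular velocity in the
#' sensor's local frame and 3-axis free acceleration in the earth frame.
#'
#' @param id sensor id.
#' @param time uniform time vector (s).
#' @param gyro n x 3 angular velocity (rad/s, sensor frame).
#' @param acc n x 3 free acceleration (m/s^2, earth frame).
#' @param provenance one of `"simulated"`, `"synthetic"`, `"measured_emulated"`.
#' @return An object of class `imu_trace`.
#' @export
imu_trace <- function(id, time, gyro, acc,
                      provenance = c("simulated", "synthetic", "measured_emulated")) {
  provenance <- match.arg(provenance)
  time <- as.numeric(time)
  gyro <- as.matrix(gyro); acc <- as.matrix(acc)
  if (length(time) < 2) stop("imu_trace: need at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * mean(dt)) {
    stop("imu_trace: time base must be uniform")
  }
  if (nrow(gyro) != length(time) || nrow(acc) != length(time) ||
      ncol(gyro) != 3 || ncol(acc) != 3) {
    stop("imu_trace: gyro/acc must be n x 3 matching the time base")
  }
  if (any(!is.finite(gyro)) || any(!is.finite(acc))) {
    stop("imu_trace: non-finite channels")
  }
  dimnames(gyro) <- NULL
  dimnames(acc) <- NULL
  structure(list(id = id, time = time, gyro = gyro, acc = acc,
                 fs = 1 / mean(dt), provenance = provenance),
            class = "imu_trace")
}

#' @export
print.imu_trace <- function(x, ...) {
  cat(sprintf("imu_trace '%s': %d samples @ %.1f Hz, provenance %s\n",
              x$id, length(x$time), x$fs, x$provenance))
  invisible(x)
}

#' Simulate virtual IMU signals from a pose trajectory
#'
#' For each mount, the gyroscope channel is the segment's earth-frame angular
#' velocity rotated into the sensor frame, `R_sensor(t)' * omega(t)`, and the
#' accelerometer channel is the free (gravity-less) acceleration of the mount
#' point in the earth frame. Signals are produced directly on a uniform grid
#' at `fs_out`.
#'
#' @param poses a [forward_kinematics()] result (its chain/trial are used for
#'   analytic differentiation).
#' @param mounts list of [sensor_mount()]s; defaults to the mounts stored in
#'   `poses`, else [default_mounts()].
#' @param fs_out output sampling rate (Hz).
#' @param provenance provenance tag for the produced traces.
#' @return named list of [imu_trace()] objects, one per mount.
#' @export
simulate_imu <- function(poses, mounts = NULL, fs_out = 100,
                         provenance = "simulated") {
  if (fs_out <= 0) stop("simulate_imu: fs_out must be positive")
  if (is.null(mounts)) mounts <- poses$mounts
  if (is.null(mounts)) mounts <- default_mounts(poses$chain)
  for (m in mounts) {
    if (!m$segment %in% names(poses$bodies)) {
      stop("simulate_imu: unknown segment id '", m$segment, "' in mount '", m$id, "'")
    }
  }
  chain <- poses$chain; trial <- poses$trial
  t0 <- trial$time[1]; t1 <- trial$time[length(trial$time)]
  nt <- floor((t1 - t0) * fs_out + 1e-9) + 1L
  times <- t0 + (seq_len(nt) - 1L) / fs_out

  omega <- angular_velocity_at(chain, trial, times)
  st <- eval_state(trial_splines(trial), times)
  bodies_out <- fk_bodies(chain, st$angles, st$pos, st$quat)
  resolved <- lapply(mounts, function(m) list(segment = m$segment, mount = NULL))
  names(resolved) <- vapply(mounts, function(m) m$id, "")
  fine <- fine_point_positions(chain, trial, resolved,
                               stats::setNames(lapply(mounts, `[[`, "position"),
                                               names(resolved)), 1000)
  out <- lapply(seq_along(mounts), function(i) {
    m <- mounts[[i]]
    q_sensor <- quat_multiply(bodies_out[[m$segment]]$q, m$orientation)
    gyro <- quat_rotate(quat_conjugate(q_sensor), omega[[m$segment]])
    acc <- second_derivative_at(fine$times, fine$points[[m$id]], times)
    imu_trace(m$id, times, gyro, acc, provenance)
  })
  names(out) <- names(resolved)
  out
}

#' Noise parameters for measured-sensor emulation
#'
#' @param sigma_gyro white-noise std per gyro channel (rad/s).
#' @param sigma_acc white-noise std per accelerometer channel (m/s^2).
#' @param sigma_mount per-axis std of the fixed mount-misalignment rotation
#'   (degrees), drawn once per trial.
#' @param soft_tissue optional soft-tissue artifact: `NULL` (off) or a list
#'   `list(amplitude, f0, zeta)` — an exponentially damped oscillation of the
#'   thigh/shank accelerometer channels triggered at heel strikes
#'   (`amplitude` in m/s^2, `f0` in Hz, damping ratio `zeta`).
#' @return list of class `noise_params`.
#' @export
noise_params <- function(sigma_gyro = 0.03, sigma_acc = 0.2,
                         sigma_mount = 2, soft_tissue = NULL) {
  stopifnot(sigma_gyro >= 0, sigma_acc >= 0, sigma_mount >= 0)
  if (!is.null(soft_tissue)) {
    soft_tissue <- list(amplitude = soft_tissue$amplitude %||% 1,
                        f0 = soft_tissue$f0 %||% 10,
                        zeta = soft_tissue$zeta %||% 0.3)
  }
  structure(list(sigma_gyro = sigma_gyro, sigma_acc = sigma_acc,
                 sigma_mount = sigma_mount, soft_tissue = soft_tissue),
            class = "noise_params")
}

#' Emulate a measured sensor from a clean simulated trace
#'
#' Adds per-channel white Gaussian noise, a fixed random mount-misalignment
#' rotation of the gyro channels (drawn once per trial), and optionally an
#' exponentially damped oscillation at heel strikes emulating soft-tissue
#' artifact. Reproducible under `rng_seed`.
#'
#' @param trace an [imu_trace()].
#' @param noise a [noise_params()].
#' @param rng_seed integer seed.
#' @param heel_strike_times times (s) of heel strikes, used only by the
#'   soft-tissue artifact.
#' @return An [imu_trace()] with provenance `"measured_emulated"`.
#' @export
emulate_measured <- function(trace, noise = noise_params(), rng_seed = 1,
                             heel_strike_times = numeric(0)) {
  n <- length(trace$time)
  gyro <- trace$gyro; acc <- trace$acc
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(rng_seed)
  rng <- list(mis = stats::rnorm(3, 0, noise$sigma_mount) * pi / 180,
              g = matrix(stats::rnorm(3 * n, 0, noise$sigma_gyro), n, 3),
              a = matrix(stats::rnorm(3 * n, 0, noise$sigma_acc), n, 3))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  if (noise$sigma_mount > 0) {
    q_mis <- quat_multiply(
      quat_multiply(quat_from_axis_angle(c(0, 1, 0), rng$mis[1]),
                    quat_from_axis_angle(c(1, 0, 0), rng$mis[2])),
      quat_from_axis_angle(c(0, 0, 1), rng$mis[3]))[1, ]
    gyro <- quat_rotate(quat_conjugate(q_mis), gyro)
  }
  if (noise$sigma_gyro > 0) gyro <- gyro + rng$g
  if (noise$sigma_acc > 0) acc <- acc + rng$a
  st <- noise$soft_tissue
  if (!is.null(st) && trace$id %in% c("thigh", "shank") &&
      length(heel_strike_times)) {
    wd <- 2 * pi * st$f0 * sqrt(max(0, 1 - st$zeta^2))
    for (ths in heel_strike_times) {
      tau <- trace$time - ths
      active <- tau >= 0
      burst <- numeric(n)
      burst[active] <- st$amplitude *
        exp(-st$zeta * 2 * pi * st$f0 * tau[active]) * sin(wd * tau[active])
      acc[, 3] <- acc[, 3] + burst
    }
  }
  imu_trace(trace$id, trace$time, gyro, acc, "measured_emulated")
}

#' Write IMU traces to CSV files plus a manifest
#'
#' One file per sensor with columns `time, gyro_x..z, acc_x..z`, and a JSON
#' manifest recording sensor ids, sampling rates and provenance.
#'
#' @param traces named list of [imu_trace()]s.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return paths of the written files (invisibly).
#' @export
write_imu_csv <- function(traces, dir, prefix = "imu") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(traces, function(tr) {
    df <- data.frame(time = tr$time,
                     gyro_x = tr$gyro[, 1], gyro_y = tr$gyro[, 2], gyro_z = tr$gyro[, 3],
                     acc_x = tr$acc[, 1], acc_y = tr$acc[, 2], acc_z = tr$acc[, 3])
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, tr$id))
    utils::write.csv(df, p, row.names = FALSE)
    p
  }, "")
  manifest <- list(sensors = lapply(traces, function(tr) {
    list(id = tr$id, fs = tr$fs, n = length(tr$time), provenance = tr$provenance)
  }))
  jsonlite::write_json(manifest, file.path(dir, sprintf("%s_manifest.json", prefix)),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read IMU traces written by [write_imu_csv()]
#' @param dir directory containing the CSV files and manifest.
#' @param prefix file-name prefix used when writing.
#' @return named list of [imu_trace()]s.
#' @export
read_imu_csv <- function(dir, prefix = "imu") {
  manifest <- jsonlite::read_json(file.path(dir, sprintf("%s_manifest.json", prefix)))
  out <- lapply(manifest$sensors, function(s) {
    df <- utils::read.csv(file.path(dir, sprintf("%s_%s.csv", prefix, s$id)))
    imu_trace(s$id, df$time, as.matrix(df[, c("gyro_x", "gyro_y", "gyro_z")]),
              as.matrix(df[, c("acc_x", "acc_y", "acc_z")]), s$provenance)
  })
  names(out) <- vapply(manifest$sensors, `[[`, "", "id")
  out
}

#' Finite-difference oracle for virtual IMU signals
#'
#' Independent check of [simulate_imu()]: sensor orientations and positions
#' are evaluated sample-by-sample by forward kinematics only, then the
#' angular velocity is obtained by central differences of the orientation
#' sequence (axis-angle of `q(t+h) q(t-h)^-1` over `2h`) and the
#' acceleration by 5-point central second differences of the position. The
#' two boundary samples on each side are dropped.
#'
#' @param poses a [forward_kinematics()] result with sensors attached.
#' @param sensor sensor id.
#' @return list with `idx` (retained sample indices), `gyro` (sensor frame)
#'   and `acc` (earth frame) matrices.
#' @export
fd_imu_oracle <- function(poses, sensor) {
  s <- poses$sensors[[sensor]]
  if (is.null(s)) stop("fd_imu_oracle: no sensor '", sensor, "' in poses")
  q <- s$q; p <- s$p
  n <- nrow(q); h <- 1 / poses$trial$fs
  idx <- 3:(n - 2)
  # central difference of orientation: rotation from t-h to t+h in earth frame
  dq <- quat_multiply(q[idx + 1, , drop = FALSE],
                      quat_conjugate(q[idx - 1, , drop = FALSE]))
  sgn <- ifelse(dq[, 1] < 0, -1, 1)
  dq <- dq * sgn
  vn <- sqrt(rowSums(dq[, 2:4, drop = FALSE]^2))
  ang <- 2 * atan2(vn, dq[, 1])
  axis <- dq[, 2:4, drop = FALSE] / ifelse(vn > 0, vn, 1)
  w_earth <- axis * ang / (2 * h)
  gyro <- quat_rotate(quat_conjugate(q[idx, , drop = FALSE]), w_earth)
  acc <- (-p[idx + 2, , drop = FALSE] + 16 * p[idx + 1, , drop = FALSE] -
            30 * p[idx, , drop = FALSE] + 16 * p[idx - 1, , drop = FALSE] -
            p[idx - 2, , drop = FALSE]) / (12 * h^2)
  list(idx = idx, gyro = gyro, acc = acc)
}
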