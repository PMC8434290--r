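#' Cubic resampling of an IMU trace
#'
#' Interpolates all six channels onto a uniform grid at `fs_out` spanning the
#' original time range, using cubic splines.
#'
#' @param trace an [imu_trace()] with at least 4 samples.
#' @param fs_out target sampling rate (Hz).
#' @return A resampled [imu_trace()].
#' @export
resample_cubic <- function(trace, fs_out) {
  if (fs_out <= 0) stop("resample_cubic: fs_out must be positive")
  if (length(trace$time) < 4) stop("resample_cubic: need at least 4 samples")
  t0 <- trace$time[1]; t1 <- trace$time[length(trace$time)]
  nt <- floor((t1 - t0) * fs_out + 1e-9) + 1L
  times <- t0 + (seq_len(nt) - 1L) / fs_out
  interp <- function(m) {
    vapply(1:3, function(i) {
      stats::splinefun(trace$time, m[, i], method = "fmm")(times)
    }, numeric(nt))
  }
  imu_trace(trace$id, times, interp(trace$gyro), interp(trace$acc),
            trace$provenance)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order (by default) Butterworth filter applied forward and backward
#' (`signal::filtfilt`), giving zero phase lag and the squared magnitude
#' response. Applied identically to IMU channels and joint-angle targets.
#'
#' @param x numeric vector or matrix (columns are channels).
#' @param fs sampling rate (Hz); must exceed `2 * fc`.
#' @param fc cutoff frequency (Hz).
#' @param order filter order.
#' @return Filtered object of the same shape as `x`.
#' @export
butter_lowpass <- function(x, fs, fc = 6, order = 2) {
  if (fs <= 2 * fc) {
    stop("butter_lowpass: sampling rate must exceed twice the cutoff")
  }
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the plain
  # forward-backward pass (constant signals pass through exactly)
  one <- function(col) {
    n <- length(col)
    pad <- min(n - 1, ceiling(8 * fs / fc))
    ext <- c(2 * col[1] - col[(pad + 1):2],
             col,
             2 * col[n] - col[(n - 1):(n - pad)])
    y <- signal::filtfilt(bf, ext)
    y[(pad + 1):(pad + n)]
  }
  if (is.matrix(x)) {
    out <- apply(x, 2, one)
    dimnames(out) <- dimnames(x)
    out
  } else {
    one(x)
  }
}

#' Low-pass filter the joint-angle channels of a trial
#' @param trial a [kinematic_trial()].
#' @inheritParams butter_lowpass
#' @return The filtered trial.
#' @export
filter_trial <- function(trial, fc = 6, order = 2) {
  out <- trial
  out$angles <- butter_lowpass(trial$angles, trial$fs, fc, order)
  out
}

#' Low-pass filter all channels of an IMU trace
#' @param trace an [imu_trace()].
#' @inheritParams butter_lowpass
#' @return The filtered trace.
#' @export
filter_imu <- function(trace, fc = 6, order = 2) {
  tr <- trace
  tr$gyro <- butter_lowpass(trace$gyro, trace$fs, fc, order)
  tr$acc <- butter_lowpass(trace$acc, trace$fs, fc, order)
  tr
}

#' Detect heel strikes from a heel-height trajectory
#'
#' Heel strikes are local minima of the vertical heel position that fall
#' into the lowest `depth_frac` of the trajectory's height range, separated
#' by at least `min_separation` seconds. The depth criterion keeps the one
#' dominant minimum per stride and rejects the shallow dip of late swing.
#'
#' @param heel_z vertical heel position (m), or an n x 3 heel trajectory
#'   whose third column is used.
#' @param fs sampling rate (Hz).
#' @param min_separation minimum inter-strike interval (s).
#' @param depth_frac minima must lie below
#'   `min + depth_frac * (max - min)` of the trajectory.
#' @return integer vector of heel-strike sample indices (possibly empty).
#' @export
detect_heel_strikes <- function(heel_z, fs, min_separation = 0.6,
                                depth_frac = 0.12) {
  if (is.matrix(heel_z)) heel_z <- heel_z[, 3]
  rng <- max(heel_z) - min(heel_z)
  if (!is.finite(rng) || rng < 1e-9) return(integer(0))
  pk <- pracma::findpeaks(-heel_z,
                          minpeakdistance = max(1L, round(min_separation * fs)))
  if (is.null(pk)) return(integer(0))
  idx <- sort(pk[, 2])
  thresh <- min(heel_z) + depth_frac * rng
  idx[heel_z[idx] <= thresh]
}

#' Segment a continuous trial into gait cycles
#'
#' Splits a multi-stride trial at detected heel strikes (strike-to-strike
#' cycles). Cycles longer than `max_len` samples are rejected with a warning.
#'
#' @param trial a continuous [kinematic_trial()].
#' @param heel heel trajectory from [heel_trajectory()] (n x 3) or a vertical
#'   heel-position vector.
#' @param max_len maximum cycle length in samples.
#' @inheritParams detect_heel_strikes
#' @return list of per-cycle [kinematic_trial()]s, each carrying
#'   `meta$cycle_range = c(first, last)` sample indices of its source; empty
#'   (with a diagnostic warning) if fewer than 2 strikes are found.
#' @export
segment_cycles <- function(trial, heel, max_len = 200, min_separation = 0.6,
                           depth_frac = 0.12) {
  hs <- detect_heel_strikes(heel, trial$fs, min_separation, depth_frac)
  if (length(hs) < 2) {
    warning("segment_cycles: fewer than 2 heel strikes detected; no cycles")
    return(list())
  }
  out <- list()
  for (k in seq_len(length(hs) - 1)) {
    i0 <- hs[k]; i1 <- hs[k + 1]
    if (i1 - i0 + 1 > max_len) {
      warning(sprintf("segment_cycles: cycle %d (%d samples) exceeds %d; rejected",
                      k, i1 - i0 + 1, max_len))
      next
    }
    idx <- i0:i1
    cyc <- kinematic_trial(trial$time[idx], trial$angles[idx, , drop = FALSE],
                           trial$pelvis_pos[idx, , drop = FALSE],
                           trial$pelvis_quat[idx, , drop = FALSE],
                           subject = trial$subject, speed = trial$speed,
                           heel_strikes = c(1L, length(idx)),
                           meta = utils::modifyList(trial$meta,
                                                    list(cycle = k,
                                                         cycle_range = c(i0, i1))))
    out[[length(out) + 1L]] <- cyc
  }
  out
}

#' Extract the sample range of a cycle from IMU traces
#' @param traces named list of [imu_trace()]s on the same grid as the source
#'   trial.
#' @param range length-2 integer vector `c(first, last)`.
#' @return named list of sliced [imu_trace()]s.
#' @export
slice_imu <- function(traces, range) {
  idx <- range[1]:range[2]
  lapply(traces, function(tr) {
    imu_trace(tr$id, tr$time[idx], tr$gyro[idx, , drop = FALSE],
              tr$acc[idx, , drop = FALSE], tr$provenance)
  })
}

#' Sensor order of the 24 input channels
#' @export
sensor_order <- function() c("pelvis", "thigh", "shank", "foot")

#' Pack gait cycles into fixed-length training samples
#'
#' Builds the network's 200 x 24 input (sensor-major channel order: for each
#' of pelvis, thigh, shank, foot the accelerometer x,y,z then gyroscope
#' x,y,z) and 200 x 3 target (the chosen joint's flex-ext, ad-ab, int-ext),
#' zero-padded at the tail with a validity mask.
#'
#' @param cycles list of pairs `list(imu = <named list of 4 traces>,
#'   trial = <kinematic_trial>)`, each cycle at most `len` samples.
#' @param joint `"hip"` or `"knee"`.
#' @param len padded length.
#' @return list of `training_sample` objects with fields `x` (len x 24), `y`
#'   (len x 3), `mask` (length len), `subject`, `provenance`, `meta`.
#' @export
pad_and_pack <- function(cycles, joint = c("hip", "knee"), len = 200) {
  joint <- match.arg(joint)
  target_cols <- if (joint == "hip") 1:3 else 4:6
  lapply(seq_along(cycles), function(k) {
    cyc <- cycles[[k]]
    n <- n_samples(cyc$trial)
    if (n > len) {
      stop(sprintf("pad_and_pack: cycle %d has %d samples > %d", k, n, len))
    }
    x <- matrix(0, len, 24)
    for (s in seq_along(sensor_order())) {
      tr <- cyc$imu[[sensor_order()[s]]]
      if (is.null(tr) || length(tr$time) != n) {
        stop(sprintf("pad_and_pack: cycle %d lacks a matching '%s' trace",
                     k, sensor_order()[s]))
      }
      cols <- (s - 1) * 6 + 1:6
      x[1:n, cols] <- cbind(tr$acc, tr$gyro)
    }
    y <- matrix(0, len, 3)
    y[1:n, ] <- cyc$trial$angles[, target_cols]
    mask <- c(rep(1, n), rep(0, len - n))
    structure(list(x = x, y = y, mask = mask, subject = cyc$trial$subject,
                   provenance = cyc$trial$meta$provenance %||% "measured_emulated",
                   meta = cyc$trial$meta),
              class = "training_sample")
  })
}

#' Recover the unpadded cycle from a training sample
#' @param sample a `training_sample`.
#' @return list with `x` (n x 24) and `y` (n x 3) restricted to valid rows.
#' @export
unpack_sample <- function(sample) {
  n <- sum(sample$mask > 0)
  list(x = sample$x[seq_len(n), , drop = FALSE],
       y = sample$y[seq_len(n), , drop = FALSE])
}

#' Subject-wise train/test split
#'
#' @param subjects character vector of subject ids (one entry per sample or
#'   the unique ids themselves).
#' @param n_test_subjects number of held-out test subjects.
#' @param seed integer seed.
#' @return list of class `dataset_split` with `train` and `test` subject ids.
#' @export
make_split <- function(subjects, n_test_subjects, seed = 1) {
  subjects <- unique(as.character(subjects))
  if (n_test_subjects >= length(subjects)) {
    stop("make_split: n_test_subjects must be smaller than the cohort")
  }
  set.seed(seed)
  test <- sort(sample(subjects, n_test_subjects))
  structure(list(train = setdiff(subjects, test), test = test),
            class = "dataset_split")
}

#' Assemble a training-set variant from packed samples
#'
#' Filters training samples by provenance and subject for the three training
#' variants. Synthetic samples derived from test subjects are never admitted
#' (leakage guard).
#'
#' @param samples list of `training_sample`s.
#' @param split a [make_split()] result.
#' @param variant `"measured"`, `"synthetic"` or `"measured+synthetic"`.
#' @return list of training samples.
#' @export
assemble_variant <- function(samples, split,
                             variant = c("measured", "synthetic",
                                         "measured+synthetic")) {
  variant <- match.arg(variant)
  subj <- vapply(samples, `[[`, "", "subject")
  prov <- vapply(samples, `[[`, "", "provenance")
  keep_prov <- switch(variant,
                      "measured" = prov == "measured_emulated",
                      "synthetic" = prov == "synthetic",
                      "measured+synthetic" = prov %in% c("measured_emulated", "synthetic"))
  keep <- keep_prov & subj %in% split$train
  if (any(prov == "synthetic" & subj %in% split$test & keep)) {
    stop("assemble_variant: leakage — synthetic sample from a test subject")
  }
  samples[keep]
}

#' Test samples (measured role) for a split
#' @inheritParams assemble_variant
#' @return list of measured-provenance samples from test subjects.
#' @export
test_samples <- function(samples, split) {
  subj <- vapply(samples, `[[`, "", "subject")
  prov <- vapply(samples, `[[`, "", "provenance")
  samples[prov == "measured_emulated" & subj %in% split$test]
}
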