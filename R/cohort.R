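#' Normative gait template
#'
#' Keypoint-based joint-angle curves over one gait cycle (heel strike to
#' heel strike), interpolated periodically, plus cycle duration and pelvis
#' oscillation settings per speed class. All keypoints are package defaults
#' shaped after normative adult gait; they are configuration values of the
#' synthetic testbed, not measurements.
#'
#' @param speed `"slow"`, `"self_selected"` or `"fast"`.
#' @return list of class `gait_template` with `keypoints` (per-DoF matrices
#'   of cycle fraction and angle in degrees), `duration` (s), `stride_length`
#'   (m) and `pelvis` oscillation parameters.
#' @export
gait_template <- function(speed = c("self_selected", "slow", "fast")) {
  speed <- match.arg(speed)
  durations <- c(slow = 1.3, self_selected = 1.1, fast = 0.9)
  stride_lengths <- c(slow = 1.10, self_selected = 1.25, fast = 1.40)
  kp <- list(
    hip_flex   = rbind(c(0, 30), c(0.1, 28), c(0.3, 5), c(0.5, -10),
                       c(0.65, 5), c(0.85, 32), c(1, 30)),
    hip_add    = rbind(c(0, 2), c(0.1, 6), c(0.45, 3), c(0.6, -4),
                       c(0.8, -2), c(1, 2)),
    hip_rot    = rbind(c(0, -2), c(0.3, -5), c(0.6, -3), c(0.8, 2), c(1, -2)),
    knee_flex  = rbind(c(0, 5), c(0.12, 15), c(0.4, 4), c(0.62, 35),
                       c(0.72, 62), c(0.9, 15), c(1, 5)),
    knee_add   = rbind(c(0, 1), c(0.3, 2), c(0.7, 4), c(0.85, 2), c(1, 1)),
    knee_rot   = rbind(c(0, -3), c(0.3, -6), c(0.75, 5), c(1, -3)),
    ankle_flex = rbind(c(0, 0), c(0.07, -3), c(0.45, 10), c(0.62, -14),
                       c(0.8, 3), c(1, 0))
  )
  structure(list(
    speed = speed,
    duration = unname(durations[speed]),
    stride_length = unname(stride_lengths[speed]),
    keypoints = kp,
    pelvis = list(z_amp = 0.015, z_phase = 0.05,  # lowest shortly after strike
                  y_amp = 0.015, yaw_amp = 3, roll_amp = 2, pitch_amp = 1.5)
  ), class = "gait_template")
}

# periodic interpolators for the 7 template DoFs (angle as function of
# cycle fraction, any real argument)
template_functions <- function(template) {
  lapply(template$keypoints, function(kp) {
    f <- stats::splinefun(kp[, 1], kp[, 2], method = "periodic")
    function(frac) f(frac %% 1)
  })
}

#' Draw subject-specific anthropometry and gait style
#'
#' Segment lengths come from configurable normal distributions (defaults:
#' thigh N(0.42, 0.02) m, shank N(0.40, 0.02) m, hip offset N(0.12, 0.01) m,
#' foot N(0.08, 0.008) m). Gait style varies by smooth per-DoF amplitude
#' scaling (about +/-10%), angular offsets and phase shifts (about +/-3% of
#' the cycle). Draws come from the current RNG stream.
#'
#' @param id subject id string.
#' @return list of class `subject_spec` with `chain` and per-DoF style
#'   parameters.
#' @export
subject_spec <- function(id) {
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  chain <- limb_chain(
    pelvis_width = clamp(stats::rnorm(1, 0.12, 0.01), 0.09, 0.15),
    thigh = clamp(stats::rnorm(1, 0.42, 0.02), 0.34, 0.50),
    shank = clamp(stats::rnorm(1, 0.40, 0.02), 0.32, 0.48),
    foot = clamp(stats::rnorm(1, 0.08, 0.008), 0.06, 0.10)
  )
  ndof <- 7L
  list(id = id, chain = chain,
       amp = clamp(stats::rnorm(ndof, 1, 0.05), 0.9, 1.1),
       offset = clamp(stats::rnorm(ndof, 0, 1.5), -4, 4),
       phase = clamp(stats::rnorm(ndof, 0, 0.01), -0.03, 0.03),
       duration_scale = clamp(stats::rnorm(1, 1, 0.04), 0.88, 1.12))
}

# one continuous multi-stride trial for a subject at one speed
generate_trial <- function(subj, template, n_strides, fs) {
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  tf <- template_functions(template)
  n_cycles <- n_strides + 1L   # k+1 per-cycle minima bound k full strides
  d_subj <- template$duration * subj$duration_scale
  d_k <- d_subj * clamp(stats::rnorm(n_cycles, 1, 0.03), 0.91, 1.09)
  amp_k <- clamp(matrix(stats::rnorm(n_cycles * 7, 1, 0.02), n_cycles, 7), 0.94, 1.06)
  phase_k <- clamp(stats::rnorm(n_cycles, 0, 0.005), -0.015, 0.015)
  cum <- c(0, cumsum(d_k))
  times <- seq(0, cum[n_cycles + 1] - 1 / fs, by = 1 / fs)
  # C2-smooth gait phase through the cycle boundaries: cycle k spans phase
  # [k-1, k]; a piecewise-linear phase would kink every position signal at
  # each boundary and leave acceleration spikes there
  phi <- stats::splinefun(cum, 0:n_cycles, method = "natural")(times)
  k <- pmax(1L, pmin(n_cycles, floor(phi) + 1L))
  frac <- phi - (k - 1)
  # smooth blending window, zero at cycle boundaries, keeps per-stride
  # perturbations continuous across strides
  w <- (1 - cos(2 * pi * frac)) / 2
  angles <- matrix(0, length(times), 7)
  for (j in 1:7) {
    f_eval <- frac - subj$phase[j] - phase_k[k] * w
    base <- tf[[j]](f_eval)
    stride_amp <- 1 + (amp_k[cbind(k, j)] - 1) * w
    angles[, j] <- subj$amp[j] * stride_amp * base + subj$offset[j]
  }
  pv <- template$pelvis
  z0 <- subj$chain$segments$thigh$length + subj$chain$segments$shank$length + 0.07
  prog <- (k - 1 + frac) * template$stride_length
  pos <- cbind(prog + 0.01 * sin(2 * pi * frac),
               pv$y_amp * sin(2 * pi * frac),
               z0 - pv$z_amp * cos(4 * pi * (frac - pv$z_phase)))
  yaw <- pv$yaw_amp * sin(2 * pi * frac) * pi / 180
  pitch <- pv$pitch_amp * sin(4 * pi * frac) * pi / 180
  roll <- pv$roll_amp * sin(2 * pi * frac) * pi / 180
  quat <- quat_multiply(quat_multiply(quat_from_axis_angle(c(0, 0, 1), yaw),
                                      quat_from_axis_angle(c(0, 1, 0), pitch)),
                        quat_from_axis_angle(c(1, 0, 0), roll))
  trial <- kinematic_trial(times, angles, pos, quat_normalize(quat),
                           subject = subj$id, speed = template$speed)
  # ground-truth heel strikes: per-cycle argmin of heel height computed
  # through the same forward-kinematics chain (the dominant minimum of the
  # rigid-chain heel trajectory, one per generated cycle)
  heel <- heel_trajectory(forward_kinematics(subj$chain, trial))
  hs <- integer(n_cycles)
  for (b in seq_len(n_cycles)) {
    win <- which(times >= cum[b] & times < cum[b + 1])
    hs[b] <- win[which.min(heel[win, 3])]
  }
  # trim the tail shortly after the last strike so the trial does not end in
  # a partial swing (whose shallow heel dip has no following strike)
  cut <- min(length(times), hs[n_cycles] + round(0.25 * d_k[n_cycles] * fs))
  trial <- kinematic_trial(times[1:cut], angles[1:cut, , drop = FALSE],
                           pos[1:cut, , drop = FALSE],
                           quat_normalize(quat)[1:cut, , drop = FALSE],
                           subject = subj$id, speed = template$speed,
                           heel_strikes = hs)
  trial$meta <- list(boundaries = cum, provenance = "measured_emulated")
  trial
}

#' Generate a synthetic multi-subject, multi-speed gait cohort
#'
#' Stands in for a lab cohort walking at three speeds: each subject gets
#' anthropometry and a gait style drawn once, then per-trial and per-stride
#' variability on top of the normative template. Every trial carries exact
#' ground-truth heel-strike indices computed through the subject's own chain.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_speed walking trials per subject per speed.
#' @param strides_per_trial complete strides per trial.
#' @param speeds speed classes (subset of slow/self_selected/fast).
#' @param fs sampling rate (Hz).
#' @param seed integer seed; the cohort is fully reproducible.
#' @return object of class `gait_cohort`: `trials` (list of
#'   [kinematic_trial()]s), `chains` (per subject), `subjects`, and the
#'   generation settings.
#' @export
generate_cohort <- function(n_subjects = 30, trials_per_speed = 15,
                            strides_per_trial = 3,
                            speeds = c("slow", "self_selected", "fast"),
                            fs = 100, seed = 1) {
  if (n_subjects < 1) stop("generate_cohort: need at least one subject")
  bad <- setdiff(speeds, c("slow", "self_selected", "fast"))
  if (length(bad)) stop("generate_cohort: unknown speed class ", bad[1])
  set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  trials <- list()
  chains <- list()
  for (i in seq_len(n_subjects)) {
    subj <- subject_spec(subjects[i])
    chains[[subjects[i]]] <- subj$chain
    for (sp in speeds) {
      template <- gait_template(sp)
      for (tr in seq_len(trials_per_speed)) {
        trial <- generate_trial(subj, template, strides_per_trial, fs)
        trial$meta$trial_index <- tr
        trials[[length(trials) + 1L]] <- trial
      }
    }
  }
  structure(list(trials = trials, chains = chains, subjects = subjects,
                 fs = fs, seed = seed,
                 settings = list(n_subjects = n_subjects,
                                 trials_per_speed = trials_per_speed,
                                 strides_per_trial = strides_per_trial,
                                 speeds = speeds)),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("gait_cohort: %d subjects, %d trials, %d strides @ %.0f Hz\n",
              length(x$subjects), length(x$trials), cohort_stride_count(x), x$fs))
  invisible(x)
}

#' Total ground-truth stride count of a cohort
#' @param cohort a [generate_cohort()] result.
#' @export
cohort_stride_count <- function(cohort) {
  sum(vapply(cohort$trials, function(tr) max(0L, length(tr$heel_strikes) - 1L),
             integer(1)))
}

#' Build per-stride paired IMU/kinematics data from a cohort
#'
#' For every trial: simulate clean virtual IMU traces, derive a
#' noise-emulated "measured" version, low-pass filter IMU channels and joint
#' angles, segment into strike-to-strike cycles at the stored ground-truth
#' events, and emit one pair per stride.
#'
#' @param cohort a [generate_cohort()] result.
#' @param mounts sensor mounts; defaults to [default_mounts()] scaled per
#'   subject.
#' @param noise a [noise_params()]; `NULL` disables emulation (measured role
#'   equals the clean signals).
#' @param fc low-pass cutoff (Hz); `NULL` disables filtering.
#' @param seed base seed for the per-trial noise draws.
#' @return list of per-stride entries `list(trial, imu_measured, imu_clean)`,
#'   where `trial` holds the filtered angles with provenance
#'   `"measured_emulated"`.
#' @export
build_paired_dataset <- function(cohort, mounts = NULL, noise = noise_params(),
                                 fc = 6, seed = 1) {
  out <- list()
  for (ti in seq_along(cohort$trials)) {
    trial <- cohort$trials[[ti]]
    chain <- cohort$chains[[trial$subject]]
    m <- if (is.null(mounts)) default_mounts(chain) else mounts
    poses <- forward_kinematics(chain, trial, m)
    clean <- simulate_imu(poses, m, fs_out = cohort$fs)
    hs_times <- trial$time[trial$heel_strikes]
    meas <- if (is.null(noise)) {
      lapply(clean, function(tr) imu_trace(tr$id, tr$time, tr$gyro, tr$acc,
                                           "measured_emulated"))
    } else {
      lapply(seq_along(clean), function(si) {
        emulate_measured(clean[[si]], noise,
                         rng_seed = (seed + 7919L * ti + si) %% .Machine$integer.max,
                         heel_strike_times = hs_times)
      })
    }
    names(meas) <- names(clean)
    if (!is.null(fc)) {
      clean <- lapply(clean, filter_imu, fc = fc)
      meas <- lapply(meas, filter_imu, fc = fc)
      trial <- filter_trial(trial, fc = fc)
    }
    hs <- trial$heel_strikes
    for (k in seq_len(length(hs) - 1)) {
      rng <- c(hs[k], hs[k + 1])
      idx <- rng[1]:rng[2]
      cyc <- kinematic_trial(trial$time[idx], trial$angles[idx, , drop = FALSE],
                             trial$pelvis_pos[idx, , drop = FALSE],
                             trial$pelvis_quat[idx, , drop = FALSE],
                             subject = trial$subject, speed = trial$speed,
                             heel_strikes = c(1L, length(idx)),
                             meta = list(provenance = "measured_emulated",
                                         source_trial = ti, cycle = k))
      out[[length(out) + 1L]] <- list(
        trial = cyc,
        imu_measured = slice_imu(meas, rng),
        imu_clean = slice_imu(clean, rng)
      )
    }
  }
  out
}

#' Simulate clean IMU traces for a set of (augmented) cycle trials
#'
#' Regenerates the input side of each training pair from the kinematics:
#' forward kinematics of the subject's chain followed by [simulate_imu()] and
#' optional low-pass filtering. This keeps augmented pairs label-consistent:
#' the IMU signal is always derived from the (augmented) angles, never warped
#' directly.
#'
#' @param trials list of per-cycle [kinematic_trial()]s.
#' @param chains named list of per-subject [limb_chain()]s.
#' @param fs output sampling rate (Hz).
#' @param fc low-pass cutoff (Hz); `NULL` disables filtering.
#' @param provenance provenance tag for the traces.
#' @return list of `list(trial, imu)` pairs (trial angles filtered likewise).
#' @export
simulate_cycle_imu <- function(trials, chains, fs = 100, fc = 6,
                               provenance = "synthetic") {
  lapply(trials, function(cyc) {
    chain <- chains[[cyc$subject]]
    if (is.null(chain)) stop("simulate_cycle_imu: no chain for subject ", cyc$subject)
    m <- default_mounts(chain)
    poses <- forward_kinematics(chain, cyc, m)
    imu <- simulate_imu(poses, m, fs_out = fs, provenance = provenance)
    if (!is.null(fc)) {
      imu <- lapply(imu, filter_imu, fc = fc)
      cyc <- filter_trial(cyc, fc = fc)
    }
    cyc$meta$provenance <- provenance
    list(trial = cyc, imu = imu)
  })
}
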