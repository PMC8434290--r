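#' Forward kinematics of the lower-limb chain
#'
#' Computes earth-frame poses of pelvis, thigh, shank and foot (and of any
#' rigidly attached sensors) at every sample of a trial. Hip and knee
#' rotations are applied as intrinsic (Y, X, Z) Euler sequences with clinical
#' sign conventions (see [limb_chain()]); the ankle is a hinge.
#'
#' @param chain a [limb_chain()].
#' @param trial a [kinematic_trial()] (angles in degrees, 7 DoF).
#' @param mounts optional list of [sensor_mount()]s to track.
#' @return An object of class `pose_trajectory`: `time`, `bodies` (named list
#'   with `q` n x 4 and `p` n x 3 per segment), `sensors` (same layout), and
#'   the source `chain`/`trial` for derivative computations.
#' @export
forward_kinematics <- function(chain, trial, mounts = NULL) {
  if (!inherits(chain, "limb_chain")) stop("forward_kinematics: not a limb_chain")
  if (!inherits(trial, "kinematic_trial")) {
    stop("forward_kinematics: not a kinematic_trial")
  }
  ndof <- sum(vapply(chain$joints, `[[`, 0L, "dof"))
  if (ndof != ncol(trial$angles)) {
    stop("forward_kinematics: chain DoF count (", ndof,
         ") does not match trial angle columns (", ncol(trial$angles), ")")
  }
  bodies <- fk_bodies(chain, trial$angles, trial$pelvis_pos, trial$pelvis_quat)
  sensors <- fk_sensors(bodies, mounts)
  structure(list(time = trial$time, bodies = bodies, sensors = sensors,
                 chain = chain, trial = trial, mounts = mounts),
            class = "pose_trajectory")
}

#' @export
print.pose_trajectory <- function(x, ...) {
  cat(sprintf("pose_trajectory: %d samples, bodies [%s]",
              length(x$time), paste(names(x$bodies), collapse = ", ")))
  if (length(x$sensors)) {
    cat(sprintf(", sensors [%s]", paste(names(x$sensors), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

# segment poses from raw state matrices (angles in degrees)
fk_bodies <- function(chain, angles, pelvis_pos, pelvis_quat) {
  segs <- chain$segments
  q_pel <- pelvis_quat
  p_pel <- pelvis_pos
  q_hip <- joint_quaternion("hip", angles[, 1:3, drop = FALSE], chain)
  q_thigh <- quat_multiply(q_pel, q_hip)
  p_thigh <- p_pel + quat_rotate(q_pel, segs$thigh$offset)
  q_knee <- joint_quaternion("knee", angles[, 4:6, drop = FALSE], chain)
  q_shank <- quat_multiply(q_thigh, q_knee)
  p_shank <- p_thigh + quat_rotate(q_thigh, segs$shank$offset)
  q_ankle <- joint_quaternion("ankle", angles[, 7, drop = FALSE], chain)
  q_foot <- quat_multiply(q_shank, q_ankle)
  p_foot <- p_shank + quat_rotate(q_shank, segs$foot$offset)
  list(pelvis = list(q = q_pel, p = p_pel),
       thigh = list(q = q_thigh, p = p_thigh),
       shank = list(q = q_shank, p = p_shank),
       foot = list(q = q_foot, p = p_foot))
}

fk_sensors <- function(bodies, mounts) {
  if (is.null(mounts)) return(list())
  out <- lapply(mounts, function(m) {
    seg <- bodies[[m$segment]]
    if (is.null(seg)) stop("unknown segment id in sensor mount: ", m$segment)
    list(q = quat_multiply(seg$q, m$orientation),
         p = seg$p + quat_rotate(seg$q, m$position),
         segment = m$segment)
  })
  names(out) <- vapply(mounts, function(m) m$id, "")
  out
}

# cubic-spline representation of the trial state; angles returned in radians
trial_splines <- function(trial) {
  t0 <- trial$time
  ang <- lapply(seq_len(ncol(trial$angles)), function(i) {
    stats::splinefun(t0, trial$angles[, i] * pi / 180, method = "fmm")
  })
  pos <- lapply(1:3, function(i) stats::splinefun(t0, trial$pelvis_pos[, i], method = "fmm"))
  quat <- lapply(1:4, function(i) stats::splinefun(t0, trial$pelvis_quat[, i], method = "fmm"))
  list(angles = ang, pos = pos, quat = quat)
}

eval_state <- function(sp, times) {
  ang <- vapply(sp$angles, function(f) f(times), numeric(length(times))) * 180 / pi
  if (is.null(dim(ang))) ang <- matrix(ang, nrow = length(times))
  pos <- vapply(sp$pos, function(f) f(times), numeric(length(times)))
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = length(times))
  quat <- vapply(sp$quat, function(f) f(times), numeric(length(times)))
  if (is.null(dim(quat))) quat <- matrix(quat, nrow = length(times))
  list(angles = ang, pos = pos, quat = quat_normalize(quat))
}

resolve_body <- function(poses, body) {
  if (body %in% names(poses$bodies)) {
    list(kind = "segment", segment = body, mount = NULL)
  } else if (body %in% names(poses$sensors)) {
    m <- poses$mounts[[which(vapply(poses$mounts, function(m) m$id, "") == body)]]
    list(kind = "sensor", segment = m$segment, mount = m)
  } else {
    stop("unknown body id: ", body)
  }
}

#' Earth-frame angular velocity of a segment (or its sensor)
#'
#' Computed by exact recursive propagation down the chain,
#' `omega_child = omega_parent + R_parent * omega_joint`, where the joint
#' angular velocity follows from analytic cubic-spline derivatives of the
#' joint angles (and of the root quaternion for the pelvis). Sensors share
#' their segment's angular velocity (rigid attachment).
#'
#' @param poses a [forward_kinematics()] result.
#' @param body segment or sensor id.
#' @param times optional evaluation times; defaults to the trial's samples.
#' @return n x 3 matrix of angular velocity (rad/s, earth frame).
#' @export
body_angular_velocity <- function(poses, body, times = NULL) {
  if (length(poses$time) < 5) {
    stop("body_angular_velocity: need at least 5 samples")
  }
  seg <- resolve_body(poses, body)$segment
  if (is.null(times)) times <- poses$time
  angular_velocity_at(poses$chain, poses$trial, times)[[seg]]
}

# angular velocities of all four segments at arbitrary times (earth frame)
angular_velocity_at <- function(chain, trial, times) {
  sp <- trial_splines(trial)
  n <- length(times)
  theta <- vapply(sp$angles, function(f) f(times), numeric(n))        # rad
  dtheta <- vapply(sp$angles, function(f) f(times, deriv = 1), numeric(n))
  if (is.null(dim(theta))) { theta <- matrix(theta, n); dtheta <- matrix(dtheta, n) }
  q_raw <- vapply(sp$quat, function(f) f(times), numeric(n))
  dq <- vapply(sp$quat, function(f) f(times, deriv = 1), numeric(n))
  if (is.null(dim(q_raw))) { q_raw <- matrix(q_raw, n); dq <- matrix(dq, n) }
  q_pel <- quat_normalize(q_raw)
  w_pel <- 2 * quat_multiply(dq, quat_conjugate(q_raw))[, 2:4, drop = FALSE] /
    rowSums(q_raw^2)

  ey <- c(0, 1, 0); ex <- c(1, 0, 0); ez <- c(0, 0, 1)
  joint_omega <- function(joint, th, dth) {
    j <- chain$joints[[joint]]
    if (j$dof == 3L) {
      q1 <- quat_from_axis_angle(ey, j$signs[1] * th[, 1])
      q12 <- quat_multiply(q1, quat_from_axis_angle(ex, j$signs[2] * th[, 2]))
      a1 <- matrix(ey, n, 3, byrow = TRUE) * j$signs[1]
      a2 <- quat_rotate(q1, ex * j$signs[2])
      a3 <- quat_rotate(q12, ez * j$signs[3])
      a1 * dth[, 1] + a2 * dth[, 2] + a3 * dth[, 3]
    } else {
      matrix(ey, n, 3, byrow = TRUE) * j$signs[1] * dth[, 1]
    }
  }
  # parent-frame joint rates rotated into earth frame and accumulated
  q_thigh <- quat_multiply(q_pel, joint_quaternion("hip", theta[, 1:3] * 180 / pi, chain))
  q_shank <- quat_multiply(q_thigh, joint_quaternion("knee", theta[, 4:6] * 180 / pi, chain))
  w_thigh <- w_pel + quat_rotate(q_pel, joint_omega("hip", theta[, 1:3, drop = FALSE],
                                                    dtheta[, 1:3, drop = FALSE]))
  w_shank <- w_thigh + quat_rotate(q_thigh, joint_omega("knee", theta[, 4:6, drop = FALSE],
                                                        dtheta[, 4:6, drop = FALSE]))
  w_foot <- w_shank + quat_rotate(q_shank, joint_omega("ankle", theta[, 7, drop = FALSE],
                                                       dtheta[, 7, drop = FALSE]))
  list(pelvis = w_pel, thigh = w_thigh, shank = w_shank, foot = w_foot)
}

#' Free acceleration of a body-fixed point
#'
#' Second time-derivative of the earth-frame position of a point fixed in a
#' segment (or sensor) frame; gravity is not added (free acceleration). The
#' point trajectory is evaluated on an internal 1000 Hz grid from the trial's
#' spline representation and differentiated twice analytically through a
#' cubic spline.
#'
#' @inheritParams body_angular_velocity
#' @param local_point 3-vector in the body's frame (m).
#' @param fs_internal internal differentiation rate (Hz).
#' @return n x 3 matrix of accelerations (m/s^2, earth frame).
#' @export
point_acceleration <- function(poses, body, local_point = c(0, 0, 0),
                               times = NULL, fs_internal = 1000) {
  if (length(poses$time) < 7) {
    stop("point_acceleration: need at least 7 samples")
  }
  if (length(local_point) != 3 || any(!is.finite(local_point))) {
    stop("point_acceleration: local point must be a finite 3-vector")
  }
  if (is.null(times)) times <- poses$time
  b <- resolve_body(poses, body)
  fine <- fine_point_positions(poses$chain, poses$trial,
                               stats::setNames(list(b), "pt"),
                               list(pt = local_point), fs_internal)
  second_derivative_at(fine$times, fine$points$pt, times)
}

# earth-frame positions of named (body, point) pairs on a fine uniform grid
fine_point_positions <- function(chain, trial, resolved, points, fs_internal) {
  t0 <- trial$time[1]; t1 <- trial$time[length(trial$time)]
  nf <- max(8L, ceiling((t1 - t0) * fs_internal) + 1L)
  tf <- seq(t0, t1, length.out = nf)
  st <- eval_state(trial_splines(trial), tf)
  bodies <- fk_bodies(chain, st$angles, st$pos, st$quat)
  pts <- lapply(names(resolved), function(nm) {
    b <- resolved[[nm]]
    seg <- bodies[[b$segment]]
    if (is.null(b$mount)) {
      seg$p + quat_rotate(seg$q, points[[nm]])
    } else {
      qs <- quat_multiply(seg$q, b$mount$orientation)
      ps <- seg$p + quat_rotate(seg$q, b$mount$position)
      ps + quat_rotate(qs, points[[nm]])
    }
  })
  names(pts) <- names(resolved)
  list(times = tf, points = pts, bodies = bodies)
}

second_derivative_at <- function(tf, p, times) {
  out <- vapply(1:3, function(i) {
    stats::splinefun(tf, p[, i], method = "fmm")(times, deriv = 2)
  }, numeric(length(times)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(times))
  out
}

#' Earth-frame heel-point trajectory
#'
#' Position of the chain's heel point (fixed in the foot frame), used
#' downstream for heel-strike detection and gait-cycle segmentation.
#'
#' @param poses a [forward_kinematics()] result.
#' @param chain the [limb_chain()] carrying the heel offset; defaults to the
#'   chain stored in `poses`.
#' @return n x 3 matrix of heel positions (m).
#' @export
heel_trajectory <- function(poses, chain = poses$chain) {
  foot <- poses$bodies$foot
  if (is.null(foot)) stop("heel_trajectory: no foot body in pose trajectory")
  foot$p + quat_rotate(foot$q, chain$heel_offset)
}
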