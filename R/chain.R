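#' Lower-limb rigid-body chain
#'
#' Defines the serial chain pelvis -> thigh -> shank -> foot for the left
#' lower limb. Each segment frame has its origin at the proximal joint center
#' with the distal joint center at `(0, 0, -L)` in the neutral pose. The earth
#' frame is X = walking direction, Y = left, Z = up.
#'
#' Joint rotations are intrinsic Euler sequences about the (mediolateral,
#' anteroposterior, longitudinal) axes, i.e. (Y, X, Z) of the parent frame,
#' with per-joint axis signs chosen so that positive angles carry their
#' clinical meaning for a left limb: hip/knee/ankle flexion, hip/knee
#' adduction, hip/knee internal rotation are all positive. The hip and knee
#' have 3 rotational DoF, the ankle is a 1-DoF hinge (dorsiflexion positive);
#' 7 DoF in total.
#'
#' @param pelvis_width distance from pelvis origin to the left hip joint
#'   center along +Y (m).
#' @param thigh,shank thigh (hip-knee) and shank (knee-ankle) lengths (m).
#' @param foot ankle-to-sole reference length along the segment -Z axis (m).
#' @param heel_offset heel-point position in the foot frame (m); used for
#'   gait-event detection.
#' @return An object of class `limb_chain`.
#' @examples
#' chain <- limb_chain()
#' chain$segments$thigh$length
#' @export
limb_chain <- function(pelvis_width = 0.12, thigh = 0.42, shank = 0.40,
                       foot = 0.08, heel_offset = c(-0.06, 0, -0.05)) {
  lens <- c(pelvis_width = pelvis_width, thigh = thigh, shank = shank, foot = foot)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("limb_chain: all segment lengths must be positive and finite")
  }
  if (length(heel_offset) != 3 || any(!is.finite(heel_offset))) {
    stop("limb_chain: heel_offset must be a finite 3-vector")
  }
  structure(list(
    segments = list(
      pelvis = list(parent = NA_character_, offset = c(0, 0, 0)),
      thigh  = list(parent = "pelvis", offset = c(0, pelvis_width, 0),
                    length = thigh),
      shank  = list(parent = "thigh", offset = c(0, 0, -thigh),
                    length = shank),
      foot   = list(parent = "shank", offset = c(0, 0, -shank),
                    length = foot)
    ),
    # axis signs for the intrinsic (Y, X, Z) = (flex, add, rot) sequence
    joints = list(
      hip   = list(segment = "thigh", dof = 3L, signs = c(-1, -1, -1),
                   angle_cols = 1:3),
      knee  = list(segment = "shank", dof = 3L, signs = c(1, -1, -1),
                   angle_cols = 4:6),
      ankle = list(segment = "foot", dof = 1L, signs = c(-1, NA, NA),
                   angle_cols = 7L)
    ),
    heel_offset = as.numeric(heel_offset)
  ), class = "limb_chain")
}

#' @export
print.limb_chain <- function(x, ...) {
  cat("Lower-limb rigid-body chain (left): pelvis -> thigh -> shank -> foot\n")
  cat(sprintf("  hip offset %.3f m, thigh %.3f m, shank %.3f m, foot %.3f m\n",
              x$segments$thigh$offset[2], x$segments$thigh$length,
              x$segments$shank$length, x$segments$foot$length))
  cat(sprintf("  heel point at (%.3f, %.3f, %.3f) m in foot frame\n",
              x$heel_offset[1], x$heel_offset[2], x$heel_offset[3]))
  invisible(x)
}

#' Rigid IMU mount on a segment
#'
#' @param segment one of `"pelvis"`, `"thigh"`, `"shank"`, `"foot"`.
#' @param position mount position in the segment frame (m).
#' @param orientation segment-to-sensor rotation, either a unit quaternion
#'   (length 4, scalar first) or intrinsic (Y, X, Z) Euler angles in degrees
#'   (length 3).
#' @param id sensor identifier; defaults to the segment name.
#' @return An object of class `sensor_mount`.
#' @export
sensor_mount <- function(segment, position = c(0, 0, 0),
                         orientation = c(1, 0, 0, 0), id = segment) {
  segment <- match.arg(segment, c("pelvis", "thigh", "shank", "foot"))
  if (length(orientation) == 3) {
    a <- orientation * pi / 180
    orientation <- quat_multiply(
      quat_multiply(quat_from_axis_angle(c(0, 1, 0), a[1]),
                    quat_from_axis_angle(c(1, 0, 0), a[2])),
      quat_from_axis_angle(c(0, 0, 1), a[3]))[1, ]
  }
  if (length(orientation) != 4 ||
      abs(sqrt(sum(orientation^2)) - 1) > 1e-6) {
    stop("sensor_mount: orientation must be a unit quaternion or Euler triple")
  }
  structure(list(id = id, segment = segment, position = as.numeric(position),
                 orientation = as.numeric(orientation) /
                   sqrt(sum(orientation^2))),
            class = "sensor_mount")
}

#' Default four-sensor configuration
#'
#' One sensor per segment: posterior pelvis, lateral thigh, lateral shank,
#' dorsal foot, each with a small fixed rotation. These placements are
#' package defaults for the synthetic testbed, not measured positions.
#'
#' @param chain a [limb_chain()]; mount positions scale with its lengths.
#' @return A named list of [sensor_mount()] objects.
#' @export
default_mounts <- function(chain = limb_chain()) {
  list(
    pelvis = sensor_mount("pelvis", c(-0.09, 0, 0.02), c(0, 0, 5)),
    thigh  = sensor_mount("thigh", c(0, 0.05, -0.55 * chain$segments$thigh$length),
                          c(0, 5, -8)),
    shank  = sensor_mount("shank", c(0, 0.04, -0.35 * chain$segments$shank$length),
                          c(0, 3, -5)),
    foot   = sensor_mount("foot", c(0.05, 0, -0.03), c(-10, 0, 0))
  )
}

#' Read a chain + mount configuration from YAML
#'
#' The file may contain a `chain:` block (fields of [limb_chain()]) and a
#' `mounts:` list whose entries have `segment`, `position`, `orientation`
#' (quaternion or Euler degrees) and optional `id`.
#'
#' @param path YAML file path.
#' @return list with elements `chain` and `mounts`.
#' @export
read_chain_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  chain <- do.call(limb_chain, cfg$chain %||% list())
  mounts <- if (is.null(cfg$mounts)) default_mounts(chain) else
    lapply(cfg$mounts, function(m) {
      sensor_mount(m$segment, as.numeric(m$position %||% c(0, 0, 0)),
                   as.numeric(m$orientation %||% c(1, 0, 0, 0)),
                   id = m$id %||% m$segment)
    })
  names(mounts) <- vapply(mounts, `[[`, "", "id")
  list(chain = chain, mounts = mounts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quaternion for one joint of the chain from clinical angles
#'
#' @param joint `"hip"`, `"knee"` or `"ankle"`.
#' @param angles n x dof matrix of angles in degrees (flex, add, rot order
#'   for 3-DoF joints).
#' @param chain a [limb_chain()].
#' @return n x 4 matrix of parent-to-child quaternions.
#' @export
joint_quaternion <- function(joint, angles, chain = limb_chain()) {
  j <- chain$joints[[joint]]
  if (is.null(j)) stop("unknown joint: ", joint)
  if (is.null(dim(angles))) angles <- matrix(angles, ncol = j$dof)
  if (ncol(angles) != j$dof) stop("joint_quaternion: wrong DoF count for ", joint)
  a <- angles * pi / 180
  q <- quat_from_axis_angle(c(0, 1, 0), j$signs[1] * a[, 1])
  if (j$dof == 3L) {
    q <- quat_multiply(q, quat_from_axis_angle(c(1, 0, 0), j$signs[2] * a[, 2]))
    q <- quat_multiply(q, quat_from_axis_angle(c(0, 0, 1), j$signs[3] * a[, 3]))
  }
  q
}

#' Clinical angles from a joint rotation
#'
#' Inverse of [joint_quaternion()]: extracts the intrinsic (Y, X, Z) Euler
#' angles and removes the per-joint axis signs. Valid away from the gimbal
#' singularity (|adduction| = 90 degrees).
#'
#' @inheritParams joint_quaternion
#' @param q n x 4 matrix of parent-to-child quaternions.
#' @return n x dof matrix of angles in degrees.
#' @export
joint_angles_from_quaternion <- function(joint, q, chain = limb_chain()) {
  j <- chain$joints[[joint]]
  if (is.null(j)) stop("unknown joint: ", joint)
  q <- as_quat_matrix(q)
  n <- nrow(q)
  out <- matrix(0, n, j$dof)
  for (i in seq_len(n)) {
    R <- quat_to_matrix(q[i, ])
    if (j$dof == 3L) {
      # R = Ry(a) Rx(b) Rz(c):  R[2,3] = -sin b
      b <- asin(max(-1, min(1, -R[2, 3])))
      a <- atan2(R[1, 3], R[3, 3])
      cc <- atan2(R[2, 1], R[2, 2])
      out[i, ] <- c(a, b, cc) / j$signs * 180 / pi
    } else {
      out[i, 1] <- atan2(R[1, 3], R[3, 3]) / j$signs[1] * 180 / pi
    }
  }
  out
}
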