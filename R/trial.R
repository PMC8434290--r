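#' Joint-angle column order
#'
#' Fixed DoF order used by every function in the package: hip flexion-
#' extension, hip adduction-abduction, hip internal-external rotation, the
#' same three for the knee, then ankle flexion.
#' @export
angle_columns <- function() {
  c("hip_flex", "hip_add", "hip_rot",
    "knee_flex", "knee_add", "knee_rot", "ankle_flex")
}

#' Single- or multi-stride joint-angle trial
#'
#' The label side of every training pair: a uniformly sampled time base, the
#' 7 joint-angle channels (degrees) and the pelvis root pose (earth frame).
#'
#' @param time strictly increasing, uniformly spaced time vector (s).
#' @param angles n x 7 matrix of joint angles in degrees, columns as
#'   [angle_columns()].
#' @param pelvis_pos n x 3 pelvis origin position (m, earth frame).
#' @param pelvis_quat n x 4 pelvis orientation (unit quaternions, body-to-earth).
#'   Defaults to identity.
#' @param subject,speed stride metadata (subject id, speed class).
#' @param heel_strikes integer sample indices of heel strikes, if known.
#' @param meta free-form metadata list (augmentation method, source id, ...).
#' @return An object of class `kinematic_trial`.
#' @export
kinematic_trial <- function(time, angles, pelvis_pos = NULL, pelvis_quat = NULL,
                            subject = NA_character_, speed = NA_character_,
                            heel_strikes = integer(0), meta = list()) {
  time <- as.numeric(time)
  n <- length(time)
  if (n < 2) stop("kinematic_trial: need at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * mean(dt)) {
    stop("kinematic_trial: time base must be strictly increasing and uniform")
  }
  if (is.null(dim(angles))) angles <- matrix(angles, nrow = n)
  angles <- as.matrix(angles)
  if (nrow(angles) != n || ncol(angles) != 7) {
    stop("kinematic_trial: angles must be n x 7 (got ",
         nrow(angles), " x ", ncol(angles), ")")
  }
  if (any(!is.finite(angles))) stop("kinematic_trial: non-finite joint angles")
  colnames(angles) <- angle_columns()
  if (is.null(pelvis_pos)) pelvis_pos <- matrix(0, n, 3)
  pelvis_pos <- as.matrix(pelvis_pos)
  if (is.null(pelvis_quat)) pelvis_quat <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  pelvis_quat <- as_quat_matrix(pelvis_quat)
  if (nrow(pelvis_pos) != n || ncol(pelvis_pos) != 3 ||
      nrow(pelvis_quat) != n) {
    stop("kinematic_trial: pelvis pose dimensions do not match time base")
  }
  if (any(!is.finite(pelvis_pos)) || any(!is.finite(pelvis_quat))) {
    stop("kinematic_trial: non-finite pelvis pose")
  }
  if (any(abs(sqrt(rowSums(pelvis_quat^2)) - 1) > 1e-9)) {
    stop("kinematic_trial: pelvis quaternions must be unit norm (1e-9)")
  }
  dimnames(pelvis_pos) <- NULL
  dimnames(pelvis_quat) <- NULL
  fs <- 1 / mean(dt)
  structure(list(time = time, angles = angles, pelvis_pos = pelvis_pos,
                 pelvis_quat = pelvis_quat, fs = fs, subject = subject,
                 speed = speed, heel_strikes = as.integer(heel_strikes),
                 meta = meta),
            class = "kinematic_trial")
}

#' @export
print.kinematic_trial <- function(x, ...) {
  cat(sprintf("kinematic_trial: %d samples @ %.1f Hz (%.2f s)",
              length(x$time), x$fs, diff(range(x$time))))
  if (!is.na(x$subject)) cat(sprintf(", subject %s", x$subject))
  if (!is.na(x$speed)) cat(sprintf(", speed %s", x$speed))
  if (length(x$heel_strikes)) cat(sprintf(", %d heel strikes", length(x$heel_strikes)))
  if (!is.null(x$meta$method)) cat(sprintf(", method %s", x$meta$method))
  cat("\n")
  invisible(x)
}

#' Number of samples in a trial
#' @param trial a [kinematic_trial()].
#' @export
n_samples <- function(trial) length(trial$time)

#' Write a trial to an OpenSim-style .mot/.sto file
#'
#' Tab-separated text with a `nRows`/`nColumns`/`inDegrees` header and a
#' first column `time`. The 7 joint-angle columns are followed by the pelvis
#' position (`pelvis_tx/ty/tz`) and orientation quaternion
#' (`pelvis_qw/qx/qy/qz`).
#'
#' @param trial a [kinematic_trial()].
#' @param path output file path.
#' @export
write_mot <- function(trial, path) {
  dat <- cbind(time = trial$time, trial$angles,
               pelvis_tx = trial$pelvis_pos[, 1],
               pelvis_ty = trial$pelvis_pos[, 2],
               pelvis_tz = trial$pelvis_pos[, 3],
               pelvis_qw = trial$pelvis_quat[, 1],
               pelvis_qx = trial$pelvis_quat[, 2],
               pelvis_qy = trial$pelvis_quat[, 3],
               pelvis_qz = trial$pelvis_quat[, 4])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("Coordinates", "version=1",
               sprintf("nRows=%d", nrow(dat)),
               sprintf("nColumns=%d", ncol(dat)),
               "inDegrees=yes", "endheader",
               paste(colnames(dat), collapse = "\t")), con)
  utils::write.table(format(dat, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a trial from an OpenSim-style .mot/.sto file
#'
#' Accepts any .mot/.sto whose data block contains a `time` column and the 7
#' joint-angle columns of [angle_columns()]; pelvis pose columns
#' (`pelvis_tx..tz`, `pelvis_qw..qz`) are used when present and default to a
#' static identity root otherwise. Files with `inDegrees=no` are converted
#' from radians.
#'
#' @param path input file path.
#' @param subject,speed optional metadata to attach.
#' @return A [kinematic_trial()].
#' @export
read_mot <- function(path, subject = NA_character_, speed = NA_character_) {
  lines <- readLines(path)
  hend <- which(trimws(tolower(lines)) == "endheader")
  if (length(hend) != 1) stop("read_mot: no endheader line in ", path)
  header <- lines[seq_len(hend - 1)]
  in_deg <- !any(grepl("inDegrees\\s*=\\s*no", header, ignore.case = TRUE))
  dat <- utils::read.table(text = lines[(hend + 1):length(lines)],
                           header = TRUE, sep = "\t", check.names = FALSE)
  if (!"time" %in% names(dat)) stop("read_mot: no time column in ", path)
  missing <- setdiff(angle_columns(), names(dat))
  if (length(missing)) {
    stop("read_mot: missing joint-angle columns: ", paste(missing, collapse = ", "))
  }
  angles <- as.matrix(dat[, angle_columns()])
  if (!in_deg) angles <- angles * 180 / pi
  n <- nrow(dat)
  pos <- if (all(c("pelvis_tx", "pelvis_ty", "pelvis_tz") %in% names(dat))) {
    as.matrix(dat[, c("pelvis_tx", "pelvis_ty", "pelvis_tz")])
  } else NULL
  quat <- if (all(c("pelvis_qw", "pelvis_qx", "pelvis_qy", "pelvis_qz") %in% names(dat))) {
    quat_normalize(as.matrix(dat[, c("pelvis_qw", "pelvis_qx", "pelvis_qy", "pelvis_qz")]))
  } else NULL
  kinematic_trial(dat$time, angles, pos, quat, subject = subject, speed = speed)
}
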