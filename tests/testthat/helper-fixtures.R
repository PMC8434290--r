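# Shared fixtures; everything is generated in code, nothing is stored.

# band-limited random 7-DoF trial with a moving pelvis root
make_smooth_trial <- function(n = 1001, fs = 1000, seed = 1, amp = 15) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  ang <- vapply(1:7, function(j) {
    a <- stats::runif(3, -amp, amp)
    f <- stats::runif(3, 0.5, 2)
    ph <- stats::runif(3, 0, 2 * pi)
    rowSums(vapply(1:3, function(k) a[k] * sin(2 * pi * f[k] * t + ph[k]),
                   numeric(n)))
  }, numeric(n))
  rpy <- vapply(1:3, function(j) {
    0.1 * sin(2 * pi * stats::runif(1, 0.5, 1.5) * t + stats::runif(1, 0, 6))
  }, numeric(n))
  q <- quat_multiply(quat_multiply(quat_from_axis_angle(c(0, 0, 1), rpy[, 1]),
                                   quat_from_axis_angle(c(0, 1, 0), rpy[, 2])),
                     quat_from_axis_angle(c(1, 0, 0), rpy[, 3]))
  pos <- cbind(1.2 * t + 0.02 * sin(2 * pi * t),
               0.02 * sin(2 * pi * 0.8 * t),
               0.9 + 0.02 * cos(2 * pi * 2 * t))
  kinematic_trial(t, ang, pos, quat_normalize(q))
}

# constant-pose trial
make_static_trial <- function(n = 101, fs = 100, angles = rep(0, 7)) {
  kinematic_trial((seq_len(n) - 1) / fs, matrix(angles, n, 7, byrow = TRUE))
}

# small cohort + paired dataset, built once per test session
local_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(local_cache[[key]])) local_cache[[key]] <- force(expr)
  local_cache[[key]]
}

small_cohort <- function() {
  cached("small_cohort",
         generate_cohort(n_subjects = 4, trials_per_speed = 1,
                         strides_per_trial = 3, seed = 42))
}

small_pairs_clean <- function() {
  cached("small_pairs_clean",
         build_paired_dataset(small_cohort(), noise = NULL, seed = 42))
}

# independent Euler extraction oracle via rotation matrices (YXZ intrinsic,
# written without reference to the package's own extraction code)
oracle_yxz_angles <- function(R) {
  b <- asin(max(-1, min(1, -R[2, 3])))
  a <- atan2(R[1, 3], R[3, 3])
  cc <- atan2(R[2, 1], R[2, 2])
  c(a, b, cc) * 180 / pi
}
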