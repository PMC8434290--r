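chain <- limb_chain()

test_that("neutral pose places segments along -Z with identity orientations", {
  trial <- make_static_trial()
  poses <- forward_kinematics(chain, trial)
  expect_equal(poses$bodies$thigh$p[1, ], c(0, 0.12, 0), tolerance = 1e-12)
  expect_equal(poses$bodies$shank$p[1, ], c(0, 0.12, -0.42), tolerance = 1e-12)
  expect_equal(poses$bodies$foot$p[1, ], c(0, 0.12, -0.82), tolerance = 1e-12)
  for (b in names(poses$bodies)) {
    expect_lt(max(abs(poses$bodies[[b]]$q[1, ] - c(1, 0, 0, 0))), 1e-12)
  }
})

test_that("90 degree knee flexion makes shank perpendicular to thigh, pointing backward", {
  a <- rep(0, 7); a[4] <- 90
  poses <- forward_kinematics(chain, make_static_trial(angles = a))
  z_thigh <- quat_rotate(poses$bodies$thigh$q[1, , drop = FALSE], c(0, 0, -1))
  z_shank <- quat_rotate(poses$bodies$shank$q[1, , drop = FALSE], c(0, 0, -1))
  expect_equal(acos(sum(z_thigh * z_shank)) * 180 / pi, 90, tolerance = 1e-9)
  expect_equal(as.numeric(z_shank), c(-1, 0, 0), tolerance = 1e-9)
})

test_that("forward kinematics round-trips random joint angles through Euler extraction", {
  set.seed(10)
  worst <- 0
  for (i in 1:1000) {
    ang <- stats::runif(7, -120, 120)
    ang[c(2, 5)] <- stats::runif(2, -79, 79)    # away from gimbal lock
    trial <- make_static_trial(n = 2, fs = 100, angles = ang)
    poses <- forward_kinematics(chain, trial)
    # child orientation composed with inverse parent = joint rotation
    q_hip <- quat_multiply(quat_conjugate(poses$bodies$pelvis$q[1, , drop = FALSE]),
                           poses$bodies$thigh$q[1, , drop = FALSE])
    q_knee <- quat_multiply(quat_conjugate(poses$bodies$thigh$q[1, , drop = FALSE]),
                            poses$bodies$shank$q[1, , drop = FALSE])
    signs_hip <- c(-1, -1, -1); signs_knee <- c(1, -1, -1)
    rec_hip <- oracle_yxz_angles(quat_to_matrix(q_hip[1, ])) / signs_hip
    rec_knee <- oracle_yxz_angles(quat_to_matrix(q_knee[1, ])) / signs_knee
    worst <- max(worst, abs(rec_hip - ang[1:3]), abs(rec_knee - ang[4:6]))
  }
  expect_lt(worst, 1e-8)
})

test_that("angular velocity is zero for a static pose and exact for a constant-rate hinge", {
  poses <- forward_kinematics(chain, make_static_trial())
  expect_lt(max(abs(body_angular_velocity(poses, "foot"))), 1e-9)

  n <- 1001; t <- (seq_len(n) - 1) / 1000
  a <- matrix(0, n, 7); a[, 7] <- t * 180 / pi          # ankle at 1 rad/s
  poses <- forward_kinematics(chain, kinematic_trial(t, a))
  w_foot <- body_angular_velocity(poses, "foot")
  w_shank <- body_angular_velocity(poses, "shank")
  expect_equal(sqrt(rowSums(w_foot^2)), rep(1, n), tolerance = 1e-6)
  expect_lt(max(abs(w_shank)), 1e-9)
})

test_that("angular velocity needs at least 5 samples", {
  trial <- make_static_trial(n = 3)
  poses <- forward_kinematics(chain, trial)
  expect_error(body_angular_velocity(poses, "foot"), "5 samples")
})

test_that("analytic velocity and acceleration match finite differences on smooth trials", {
  mounts <- default_mounts(chain)
  for (s in 1:5) {
    trial <- make_smooth_trial(n = 801, fs = 1000, seed = s)
    poses <- forward_kinematics(chain, trial, mounts)
    sim <- simulate_imu(poses, mounts, fs_out = trial$fs)
    for (id in c("pelvis", "foot")) {
      fd <- fd_imu_oracle(poses, id)
      expect_lt(max(abs(sim[[id]]$gyro[fd$idx, ] - fd$gyro)), 1e-3)
      expect_lt(max(abs(sim[[id]]$acc[fd$idx, ] - fd$acc)), 1e-2)
    }
  }
})

test_that("point acceleration recovers closed forms", {
  n <- 1001; t <- (seq_len(n) - 1) / 1000
  # constant-velocity translation: zero acceleration
  pos <- cbind(0.5 * t, -0.2 * t, 0.9 + 0.1 * t)
  poses <- forward_kinematics(chain, kinematic_trial(t, matrix(0, n, 7), pos))
  acc <- point_acceleration(poses, "foot", c(0.02, 0.01, -0.03))
  expect_lt(max(abs(acc[50:950, ])), 1e-6)
  # centripetal acceleration on a constant-rate hinge: |a| = w^2 r
  a <- matrix(0, n, 7); a[, 7] <- t * 2 * 180 / pi      # 2 rad/s
  poses <- forward_kinematics(chain, kinematic_trial(t, a))
  r <- 0.1
  acc <- point_acceleration(poses, "foot", c(r, 0, 0))
  mag <- sqrt(rowSums(acc[100:900, ]^2))
  expect_equal(mag, rep(4 * r, length(mag)), tolerance = 1e-4)
})

test_that("rotating the earth frame rotates poses, velocities and accelerations (equivariance)", {
  trial <- make_smooth_trial(n = 501, fs = 500, seed = 7)
  Q <- quat_from_axis_angle(c(1, 2, 2) / 3, 1.1)[1, ]
  trial_rot <- kinematic_trial(trial$time, trial$angles,
                               quat_rotate(Q, trial$pelvis_pos),
                               quat_multiply(Q, trial$pelvis_quat))
  p1 <- forward_kinematics(chain, trial)
  p2 <- forward_kinematics(chain, trial_rot)
  expect_equal(p2$bodies$foot$p, quat_rotate(Q, p1$bodies$foot$p), tolerance = 1e-9)
  w1 <- body_angular_velocity(p1, "shank")
  w2 <- body_angular_velocity(p2, "shank")
  expect_equal(w2, quat_rotate(Q, w1), tolerance = 1e-9)
  a1 <- point_acceleration(p1, "shank", c(0, 0.04, -0.1))
  a2 <- point_acceleration(p2, "shank", c(0, 0.04, -0.1))
  expect_equal(a2, quat_rotate(Q, a1), tolerance = 1e-7)
})

test_that("heel trajectory transfers pelvis motion rigidly and is constant when static", {
  poses <- forward_kinematics(chain, make_static_trial())
  heel <- heel_trajectory(poses)
  expect_equal(heel, matrix(rep(heel[1, ], each = nrow(heel)), ncol = 3),
               tolerance = 1e-12)
  # pure vertical pelvis oscillation with static joints
  n <- 201; t <- (seq_len(n) - 1) / 100
  osc <- 0.05 * sin(2 * pi * t)
  trial <- kinematic_trial(t, matrix(0, n, 7), cbind(0 * t, 0 * t, 0.9 + osc))
  heel <- heel_trajectory(forward_kinematics(chain, trial))
  expect_equal(heel[, 3] - heel[1, 3], osc - osc[1], tolerance = 1e-9)
})

test_that("DoF mismatch raises a configuration error", {
  trial <- make_static_trial()
  broken <- chain
  broken$joints$ankle$dof <- 2L
  expect_error(forward_kinematics(broken, trial), "DoF count")
})
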