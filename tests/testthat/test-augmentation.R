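params <- augmentation_params()

make_cycle <- function(n = 120, fs = 100, const = NULL, seed = 1) {
  if (is.null(const)) {
    trial <- make_smooth_trial(n = n, fs = fs, seed = seed)
  } else {
    trial <- make_static_trial(n = n, fs = fs, angles = rep(const, 7))
  }
  trial
}

test_that("identity parameterizations reproduce the input exactly", {
  trial <- make_cycle(seed = 2)
  out <- magnitude_offset(trial, params, delta = 0)
  expect_equal(out$angles, trial$angles, tolerance = 0)
  out <- magnitude_warp(trial, params, knots = rep(1, 7))
  expect_lt(max(abs(out$angles - trial$angles)), 1e-12)
  out <- time_warp(trial, params, knots = rep(1, 7))
  expect_lt(max(abs(out$angles - trial$angles)), 1e-9)
  expect_lt(max(abs(out$pelvis_pos - trial$pelvis_pos)), 1e-9)
})

test_that("magnitude offset adds one constant to every column and spares the pelvis", {
  trial <- make_cycle(const = 10)
  out <- magnitude_offset(trial, params, delta = 3.2)
  expect_equal(unname(out$angles), matrix(13.2, n_samples(trial), 7), tolerance = 1e-12)
  expect_identical(out$pelvis_pos, trial$pelvis_pos)
  expect_identical(out$pelvis_quat, trial$pelvis_quat)
})

test_that("magnitude warp applies the independently evaluated spline ratio", {
  trial <- make_cycle(const = 10)
  knots <- rep(c(0.8, 1.2), length.out = 7)
  out <- magnitude_warp(trial, params, knots = knots)
  xk <- seq(trial$time[1], trial$time[n_samples(trial)], length.out = 7)
  d_oracle <- stats::splinefun(xk, knots, method = "natural")(trial$time)
  for (j in 1:7) {
    expect_equal(out$angles[, j] / trial$angles[, j], d_oracle, tolerance = 1e-10)
  }
})

test_that("zero angle columns are fixed points of the magnitude warp", {
  trial <- make_cycle(seed = 3)
  trial$angles[, 4] <- 0
  out <- magnitude_warp(trial, params, knots = stats::rnorm(7, 1, 0.2))
  expect_identical(out$angles[, 4], rep(0, n_samples(trial)))
})

test_that("warp-then-offset composition order is c*d + delta, not (c+delta)*d", {
  trial <- make_cycle(const = 10)
  set.seed(77)
  out <- offset_and_warp(trial, params)
  # replay the same RNG stream: warp knots first, then the offset
  set.seed(77)
  knots <- stats::rnorm(7, 1, 0.2)
  delta <- stats::rnorm(1, 0, 5)
  xk <- seq(trial$time[1], trial$time[n_samples(trial)], length.out = 7)
  d <- stats::splinefun(xk, knots, method = "natural")(trial$time)
  expect_equal(out$angles[, 1], 10 * d + delta, tolerance = 1e-10)
  expect_gt(max(abs(out$angles[, 1] - (10 + delta) * d)), 1e-3)
})

test_that("time warp on a cycle-fraction ramp reads back the warp map", {
  n <- 150
  trial <- make_static_trial(n = n, fs = 100)
  trial$angles[] <- matrix((seq_len(n)) / n, n, 7)
  set.seed(5)
  knots <- stats::rnorm(7, 1, 0.2)
  out <- time_warp(trial, params, knots = knots)
  s <- stats::splinefun(seq(trial$time[1], trial$time[n], length.out = 7),
                        knots, method = "natural")(trial$time)
  tau <- pmin(cumsum(s) / n, 1)
  expect_equal(out$angles[, 1], tau, tolerance = 1e-9)
})

test_that("time distortion vectors are strictly increasing for positive knots", {
  trial <- make_cycle(seed = 6)
  set.seed(9)
  for (i in 1:25) {
    knots <- abs(stats::rnorm(7, 1, 0.2)) + 0.05
    s <- gaitsynth:::distortion_vector(trial, params, knots)
    if (all(s > 0)) {
      tau <- cumsum(s) / n_samples(trial)
      expect_true(all(diff(tau) > 0))
    }
  }
})

test_that("composed warps reduce to their components at identity settings", {
  n <- 150
  ramp <- make_static_trial(n = n, fs = 100)
  ramp$angles[] <- matrix(seq_len(n) / n, n, 7)
  warped <- time_warp(ramp, params, knots = rep(1, 7))
  scaled <- magnitude_warp(warped, params, knots = rep(1.1, 7))
  expect_equal(scaled$angles, ramp$angles * 1.1, tolerance = 1e-9)
})

test_that("augment_dataset yields five tagged outputs per stride, deterministically", {
  trial <- make_cycle(seed = 8)
  out <- augment_dataset(list(trial), params, seed = 3)
  expect_length(out, 5)
  expect_setequal(vapply(out, function(x) x$meta$method, ""),
                  augmentation_methods())
  expect_true(all(vapply(out, function(x) x$meta$provenance, "") == "synthetic"))
  out2 <- augment_dataset(list(trial), params, seed = 3)
  expect_equal(lapply(out, `[[`, "angles"), lapply(out2, `[[`, "angles"),
               tolerance = 0)
  out3 <- augment_dataset(list(trial, trial, trial), params, seed = 3)
  expect_length(out3, 15)
  expect_error(augment_dataset(list(), params), "empty")
})

test_that("the operators' offset and knot draws recover their distributions", {
  base <- make_static_trial(n = 8, fs = 100, angles = rep(10, 7))
  set.seed(41)
  offs <- vapply(seq_len(1e4), function(i) {
    magnitude_offset(base, params)$angles[1, 1] - 10
  }, numeric(1))
  expect_lt(abs(mean(offs)), 0.15)
  expect_gt(stats::sd(offs), 4.85); expect_lt(stats::sd(offs), 5.15)
  # a natural spline interpolates its knots: reading the distortion at the
  # 7 knot samples recovers the raw draws
  n <- 127                                   # (n - 1) divisible by 6
  ones <- make_static_trial(n = n, fs = 100, angles = rep(1, 7))
  kidx <- round(seq(1, n, length.out = 7))
  set.seed(42)
  knots <- unlist(lapply(seq_len(1500), function(i) {
    magnitude_warp(ones, params)$angles[kidx, 1]
  }))
  expect_gt(length(knots), 1e4)
  expect_lt(abs(mean(knots) - 1), 0.03)
  expect_lt(abs(stats::sd(knots) - 0.2), 0.006)
})

test_that("trials shorter than the knot count are rejected", {
  short <- make_static_trial(n = 5)
  expect_error(magnitude_warp(short, params), "knot")
  expect_error(time_warp(short, params), "knot")
})
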