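test_that("cubic resampling is exact at the native rate and on polynomials", {
  n <- 101; t <- (seq_len(n) - 1) / 100
  ramp <- imu_trace("foot", t, cbind(t, 2 * t, -t), cbind(1 + t, 0 * t, t^2))
  same <- resample_cubic(ramp, 100)
  expect_equal(same$gyro, ramp$gyro, tolerance = 1e-12)
  up <- resample_cubic(ramp, 250)
  expect_equal(up$gyro[, 2], 2 * up$time, tolerance = 1e-10)
})

test_that("upsampling a 2 Hz tone from 40 to 100 Hz stays within 1e-3 of the analytic signal", {
  t40 <- (0:80) / 40
  tone <- sin(2 * pi * 2 * t40)
  tr <- imu_trace("foot", t40, cbind(tone, tone, tone), cbind(tone, tone, tone))
  up <- resample_cubic(tr, 100)
  ref <- sin(2 * pi * 2 * up$time)
  keep <- 5:(length(ref) - 5)
  expect_lt(sqrt(mean((up$gyro[keep, 1] - ref[keep])^2)), 1e-3)
})

test_that("the zero-phase Butterworth filter matches its analytic magnitude response", {
  fs <- 100; t <- (0:2999) / fs
  # DC gain is exactly one
  expect_equal(butter_lowpass(rep(2.5, 500), fs), rep(2.5, 500), tolerance = 1e-9)
  # passband: 1 Hz amplitude preserved within 2% (analog and digital
  # responses coincide well below Nyquist)
  keep <- 500:2500
  y1 <- butter_lowpass(sin(2 * pi * 1 * t), fs)
  expect_lt(abs(max(abs(y1[keep])) - 1 / (1 + (1 / 6)^4)), 0.02)
  # stopband: a 20 Hz tone is attenuated at least as strongly as the analog
  # |H|^2 = 1/(1+(20/6)^4) ~ 0.81% predicts, and matches the exact response
  # of the bilinear-designed digital filter within 20%
  y20 <- butter_lowpass(sin(2 * pi * 20 * t), fs)
  gain <- max(abs(y20[keep]))
  analog <- 1 / (1 + (20 / 6)^4)
  digital <- 1 / (1 + (tan(pi * 20 / fs) / tan(pi * 6 / fs))^4)
  expect_lt(gain, analog * 1.2)
  expect_lt(abs(gain - digital) / digital, 0.2)
})

test_that("filtering is nearly idempotent on band-limited signals", {
  fs <- 100; t <- (0:999) / fs
  x <- sin(2 * pi * 1 * t) + 0.3 * cos(2 * pi * 2 * t)
  once <- butter_lowpass(x, fs)
  twice <- butter_lowpass(once, fs)
  keep <- 100:900
  expect_lt(sqrt(mean((twice[keep] - once[keep])^2)) / sqrt(mean(once[keep]^2)), 0.01)
})

test_that("a too-low sampling rate is rejected", {
  expect_error(butter_lowpass(rnorm(100), fs = 10, fc = 6), "twice the cutoff")
})

test_that("segmentation recovers the generator's ground-truth cycles", {
  co <- small_cohort()
  trial <- co$trials[[1]]
  heel <- heel_trajectory(forward_kinematics(co$chains[[trial$subject]], trial))
  cycles <- segment_cycles(trial, heel)
  expect_length(cycles, length(trial$heel_strikes) - 1)
  for (k in seq_along(cycles)) {
    expect_lte(abs(cycles[[k]]$meta$cycle_range[1] - trial$heel_strikes[k]), 3)
    expect_lte(abs(cycles[[k]]$meta$cycle_range[2] - trial$heel_strikes[k + 1]), 3)
  }
})

test_that("a flat heel trajectory yields no cycles and a diagnostic", {
  trial <- make_static_trial(n = 300)
  expect_warning(out <- segment_cycles(trial, rep(0.05, 300)), "fewer than 2")
  expect_length(out, 0)
})

test_that("two concatenated identical strides segment into one matching cycle", {
  chain <- limb_chain()
  tmpl <- gait_template("self_selected")
  tf <- gaitsynth:::template_functions(tmpl)
  fs <- 100; n_cyc <- round(tmpl$duration * fs)
  frac <- rep((seq_len(n_cyc) - 1) / n_cyc, 3)       # three identical cycles
  n <- length(frac); t <- (seq_len(n) - 1) / fs
  ang <- vapply(tf, function(f) f(frac), numeric(n))
  z0 <- 0.89
  pos <- cbind(cumsum(rep(tmpl$stride_length / n_cyc, n)),
               0.015 * sin(2 * pi * frac),
               z0 - 0.015 * cos(4 * pi * (frac - 0.05)))
  trial <- kinematic_trial(t, ang, pos)
  heel <- heel_trajectory(forward_kinematics(chain, trial))
  cycles <- segment_cycles(trial, heel)
  expect_length(cycles, 2)
  # both cycles carry the same angle pattern
  n1 <- min(n_samples(cycles[[1]]), n_samples(cycles[[2]]))
  rms <- sqrt(mean((cycles[[1]]$angles[1:n1, ] - cycles[[2]]$angles[1:n1, ])^2))
  expect_lt(rms, 0.1)
})

test_that("packed samples have the contracted shapes, ordering and padding", {
  pairs <- small_pairs_clean()
  cycles <- lapply(pairs[1:4], function(p) list(imu = p$imu_clean, trial = p$trial))
  samples <- pad_and_pack(cycles, "hip")
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    expect_equal(dim(s$x), c(200, 24))
    expect_equal(dim(s$y), c(200, 3))
    n <- n_samples(cycles[[i]]$trial)
    expect_equal(sum(s$mask), n)
    if (n < 200) {
      expect_true(all(s$x[(n + 1):200, ] == 0))
      expect_true(all(s$y[(n + 1):200, ] == 0))
    }
    # channel order: thigh blocks are columns 7..12, acc before gyro
    expect_equal(s$x[1:n, 7:9], cycles[[i]]$imu$thigh$acc, tolerance = 1e-12)
    expect_equal(s$x[1:n, 10:12], cycles[[i]]$imu$thigh$gyro, tolerance = 1e-12)
    expect_equal(s$y[1:n, ], unname(cycles[[i]]$trial$angles[, 1:3]),
                 tolerance = 1e-12)
  }
  knee <- pad_and_pack(cycles[1], "knee")[[1]]
  expect_equal(knee$y[1:sum(knee$mask), ],
               unname(cycles[[1]]$trial$angles[, 4:6]), tolerance = 1e-12)
})

test_that("unpacking restores the unpadded cycle exactly", {
  pairs <- small_pairs_clean()
  cyc <- list(imu = pairs[[2]]$imu_clean, trial = pairs[[2]]$trial)
  s <- pad_and_pack(list(cyc), "knee")[[1]]
  u <- unpack_sample(s)
  expect_equal(nrow(u$x), n_samples(cyc$trial))
  expect_equal(u$y, unname(cyc$trial$angles[, 4:6]), tolerance = 1e-12)
})

test_that("cycles longer than the padded length are rejected by name", {
  pairs <- small_pairs_clean()
  cyc <- list(imu = pairs[[1]]$imu_clean, trial = pairs[[1]]$trial)
  expect_error(pad_and_pack(list(cyc), "hip", len = 50), "cycle 1")
})

test_that("subject-wise splits are disjoint, seeded, and leak-free", {
  subjects <- sprintf("S%02d", 1:30)
  s1 <- make_split(subjects, 3, seed = 7)
  s2 <- make_split(subjects, 3, seed = 7)
  expect_identical(s1, s2)
  expect_length(s1$train, 27)
  expect_length(s1$test, 3)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_error(make_split(subjects, 30, seed = 1), "smaller")

  # leakage guard on assembled variants
  mk <- function(subject, provenance) {
    structure(list(x = matrix(0, 4, 24), y = matrix(0, 4, 3),
                   mask = rep(1, 4), subject = subject,
                   provenance = provenance, meta = list()),
              class = "training_sample")
  }
  samples <- c(lapply(subjects, mk, provenance = "measured_emulated"),
               lapply(subjects, mk, provenance = "synthetic"))
  for (variant in c("measured", "synthetic", "measured+synthetic")) {
    got <- assemble_variant(samples, s1, variant)
    expect_false(any(vapply(got, `[[`, "", "subject") %in% s1$test))
    if (variant != "measured+synthetic") {
      expect_setequal(unique(vapply(got, `[[`, "", "provenance")),
                      if (variant == "measured") "measured_emulated" else "synthetic")
    }
  }
  tst <- test_samples(samples, s1)
  expect_setequal(unique(vapply(tst, `[[`, "", "subject")), s1$test)
})
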