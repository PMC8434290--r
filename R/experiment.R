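#' Full training-set ablation experiment on the synthetic testbed
#'
#' Runs the complete pipeline at desk scale: generate a cohort, build
#' measured-role (noise-emulated) and clean IMU/kinematics pairs, augment the
#' training subjects' strides with the five operators and regenerate
#' synthetic IMU signals from the augmented angles, then train one model per
#' training-set variant and joint and evaluate all of them on the held-out
#' subjects' measured-role data.
#'
#' @param n_subjects,trials_per_speed,strides_per_trial,speeds,fs cohort
#'   settings, see [generate_cohort()].
#' @param n_test_subjects held-out subjects.
#' @param joints joints to model (`"hip"`, `"knee"`).
#' @param variants training-set variants to compare.
#' @param noise [noise_params()] for the measured-role emulation.
#' @param epochs,hidden,n_layers desk-scale network settings applied to all
#'   models.
#' @param augment an [augmentation_params()].
#' @param seed master seed; all stage seeds derive from it.
#' @param return_models keep the trained models in the result.
#' @return list of class `gait_experiment`: `records` (per-cycle long
#'   metrics), `table` ([aggregate_table()]), `stats`
#'   ([manova_tukey()] when at least two variants are present), `split`,
#'   `counts`, and optionally `models`.
#' @export
run_experiment <- function(n_subjects = 8, trials_per_speed = 2,
                           strides_per_trial = 3,
                           speeds = c("slow", "self_selected", "fast"),
                           fs = 100, n_test_subjects = 2,
                           joints = c("hip", "knee"),
                           variants = c("measured", "synthetic",
                                        "measured+synthetic"),
                           noise = noise_params(), epochs = 25, hidden = 16,
                           n_layers = 1, augment = augmentation_params(),
                           seed = 1, return_models = FALSE) {
  if (n_subjects < 8) stop("run_experiment: need a cohort of at least 8 subjects")
  joints <- match.arg(joints, c("hip", "knee"), several.ok = TRUE)
  variants <- match.arg(variants,
                        c("measured", "synthetic", "measured+synthetic"),
                        several.ok = TRUE)
  cohort <- generate_cohort(n_subjects, trials_per_speed, strides_per_trial,
                            speeds, fs, seed)
  pairs <- build_paired_dataset(cohort, noise = noise, seed = seed + 1L)
  split <- make_split(cohort$subjects, n_test_subjects, seed + 2L)

  meas_cycles <- lapply(pairs, function(p) list(imu = p$imu_measured,
                                                trial = p$trial))
  train_idx <- vapply(pairs, function(p) p$trial$subject %in% split$train,
                      logical(1))
  src_trials <- lapply(pairs[train_idx], `[[`, "trial")
  aug_trials <- augment_dataset(src_trials, augment, seed = seed + 3L)
  syn_pairs <- simulate_cycle_imu(aug_trials, cohort$chains, fs = fs)
  syn_cycles <- lapply(syn_pairs, function(p) list(imu = p$imu, trial = p$trial))

  counts <- list(measured = length(meas_cycles),
                 measured_train = sum(train_idx),
                 synthetic = length(syn_cycles),
                 test = sum(!train_idx &
                              vapply(pairs, function(p)
                                p$trial$subject %in% split$test, logical(1))))

  records <- list()
  models <- list()
  for (joint in joints) {
    samples <- c(pad_and_pack(meas_cycles, joint), pad_and_pack(syn_cycles, joint))
    test_set <- test_samples(samples, split)
    dofs <- paste(joint, c("flex", "add", "rot"), sep = "_")
    for (variant in variants) {
      train_set <- assemble_variant(samples, split, variant)
      cfg <- bilstm_config(joint, hidden = hidden, n_layers = n_layers,
                           epochs = epochs, seed = seed + 10L)
      model <- train_bilstm(build_model(cfg), train_set)
      preds <- predict_bilstm(model, test_set)
      for (i in seq_along(test_set)) {
        s <- test_set[[i]]
        m <- cycle_metrics(preds[[i]], s$y, s$mask, dof_names = dofs)
        m$variant <- variant; m$joint <- joint
        m$subject <- s$subject; m$cycle_id <- i
        records[[length(records) + 1L]] <- m
      }
      if (return_models) models[[paste(joint, variant, sep = ".")]] <- model
    }
  }
  records <- do.call(rbind, records)
  stats_out <- if (length(variants) >= 2 &&
                   length(unique(records$cycle_id)) >= 3) {
    tryCatch(manova_tukey(records), error = function(e) NULL)
  } else NULL
  structure(list(records = records, table = aggregate_table(records),
                 stats = stats_out, split = split, counts = counts,
                 settings = list(n_subjects = n_subjects, epochs = epochs,
                                 hidden = hidden, n_layers = n_layers,
                                 seed = seed),
                 models = if (return_models) models else NULL),
            class = "gait_experiment")
}

#' @export
print.gait_experiment <- function(x, ...) {
  cat(sprintf("gait_experiment: %d measured + %d synthetic training cycles, %d test cycles\n",
              x$counts$measured_train, x$counts$synthetic, x$counts$test))
  avg <- x$table[grepl("_average$", x$table$dof), c("variant", "dof", "rmse_mean", "r_mean")]
  print(avg, row.names = FALSE)
  if (!is.null(x$stats) && !is.null(x$stats$manova)) {
    cat(sprintf("MANOVA p = %.3g\n", x$stats$manova$p_value))
  }
  invisible(x)
}

#' Mean RMSE of a joint's average row for one variant
#'
#' Convenience accessor for the headline comparison (e.g. hip-average RMSE
#' under measured vs measured+synthetic training).
#'
#' @param experiment a [run_experiment()] result.
#' @param joint `"hip"` or `"knee"`.
#' @param variant training-set variant label.
#' @return numeric scalar (degrees).
#' @export
joint_average_rmse <- function(experiment, joint, variant) {
  tb <- experiment$table
  row <- tb$variant == variant & tb$dof == paste0(joint, "_average")
  if (!any(row)) stop("joint_average_rmse: no such row")
  tb$rmse_mean[row]
}

#' Self-consistency report of the IMU simulation
#'
#' Compares the analytic simulation (recursive angular velocity, spline
#' acceleration) against the finite-difference oracle on a set of trials and
#' reports Pearson r and RMSE per sensor and channel.
#'
#' @param cohort a [generate_cohort()] result (its first `n_trials` trials
#'   are used).
#' @param n_trials number of trials to evaluate.
#' @return data.frame with columns `sensor`, `channel`, `r`, `rmse`.
#' @export
validate_simulation <- function(cohort, n_trials = 5) {
  if (!length(cohort$trials)) stop("validate_simulation: empty cohort")
  n_trials <- min(n_trials, length(cohort$trials))
  acc_sim <- list(); acc_fd <- list()
  for (ti in seq_len(n_trials)) {
    trial <- cohort$trials[[ti]]
    chain <- cohort$chains[[trial$subject]]
    mounts <- default_mounts(chain)
    poses <- forward_kinematics(chain, trial, mounts)
    sim <- simulate_imu(poses, mounts, fs_out = trial$fs)
    for (id in names(mounts)) {
      fd <- fd_imu_oracle(poses, id)
      key <- id
      a <- cbind(sim[[id]]$gyro[fd$idx, ], sim[[id]]$acc[fd$idx, ])
      b <- cbind(fd$gyro, fd$acc)
      acc_sim[[key]] <- rbind(acc_sim[[key]], a)
      acc_fd[[key]] <- rbind(acc_fd[[key]], b)
    }
  }
  channels <- c("gyro_x", "gyro_y", "gyro_z", "acc_x", "acc_y", "acc_z")
  rows <- list()
  for (id in names(acc_sim)) {
    for (j in seq_along(channels)) {
      a <- acc_sim[[id]][, j]; b <- acc_fd[[id]][, j]
      rows[[length(rows) + 1L]] <- data.frame(
        sensor = id, channel = channels[j],
        r = stats::cor(a, b), rmse = sqrt(mean((a - b)^2)))
    }
  }
  do.call(rbind, rows)
}
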