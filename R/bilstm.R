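#' BiLSTM model configuration
#'
#' Defaults follow the tuned gait models: one bidirectional LSTM layer
#' (hidden size 32 for the hip, 128 for the knee), two fully connected
#' layers, dropout 0.5 before the final layer, Adam with learning rate
#' 0.001, beta1 0.9, beta2 0.999, batch size 50, 100 epochs.
#'
#' @param joint `"hip"` or `"knee"` (sets the default hidden size).
#' @param hidden LSTM hidden size per direction.
#' @param n_layers number of stacked (Bi)LSTM layers.
#' @param dropout dropout probability before the output layer, in `[0, 1)`.
#' @param lr,beta1,beta2 Adam optimizer settings.
#' @param epochs,batch_size training schedule.
#' @param bidirectional `FALSE` gives a forward-only LSTM ablation.
#' @param masked_loss if `FALSE`, padded timesteps enter the loss too
#'   (replication mode); default is the masked loss.
#' @param seed seed for initialization, shuffling and dropout.
#' @return list of class `bilstm_config`.
#' @export
bilstm_config <- function(joint = c("hip", "knee"), hidden = NULL, n_layers = 1,
                          dropout = 0.5, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                          epochs = 100, batch_size = 50, bidirectional = TRUE,
                          masked_loss = TRUE, seed = 1) {
  joint <- match.arg(joint)
  if (is.null(hidden)) hidden <- if (joint == "hip") 32L else 128L
  if (hidden <= 0 || n_layers <= 0) {
    stop("bilstm_config: hidden size and layer count must be positive")
  }
  if (dropout < 0 || dropout >= 1) stop("bilstm_config: dropout must be in [0, 1)")
  structure(list(joint = joint, hidden = as.integer(hidden),
                 n_layers = as.integer(n_layers), dropout = dropout,
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 bidirectional = isTRUE(bidirectional),
                 masked_loss = isTRUE(masked_loss), seed = as.integer(seed)),
            class = "bilstm_config")
}

# parameter list in the fixed order the C++ engine expects
init_params <- function(cfg, n_in = 24, n_out = 3) {
  set.seed(cfg$seed)
  H <- cfg$hidden
  D <- if (cfg$bidirectional) 2L else 1L
  k <- 1 / sqrt(H)
  params <- list()
  in_l <- n_in
  for (l in seq_len(cfg$n_layers)) {
    for (d in seq_len(D)) {
      params <- c(params, list(
        matrix(stats::runif(in_l * 4 * H, -k, k), in_l, 4 * H),
        matrix(stats::runif(H * 4 * H, -k, k), H, 4 * H),
        stats::runif(4 * H, -k, k)))
    }
    in_l <- D * H
  }
  k1 <- 1 / sqrt(D * H)
  params <- c(params, list(matrix(stats::runif(D * H * H, -k1, k1), D * H, H),
                           stats::runif(H, -k1, k1)))
  k2 <- 1 / sqrt(H)
  params <- c(params, list(matrix(stats::runif(H * n_out, -k2, k2), H, n_out),
                           stats::runif(n_out, -k2, k2)))
  params
}

#' Build an untrained BiLSTM model
#'
#' @param cfg a [bilstm_config()].
#' @param n_in input channel count.
#' @param n_out output channel count.
#' @return list of class `bilstm_model` with `config`, `params` and (after
#'   training) `norm` statistics and `loss_history`.
#' @export
build_model <- function(cfg, n_in = 24, n_out = 3) {
  if (!inherits(cfg, "bilstm_config")) stop("build_model: not a bilstm_config")
  structure(list(config = cfg, params = init_params(cfg, n_in, n_out),
                 n_in = as.integer(n_in), n_out = as.integer(n_out),
                 norm = NULL, loss_history = NULL),
            class = "bilstm_model")
}

#' @export
print.bilstm_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf("bilstm_model (%s): %d layer(s) x %d hidden%s, %d parameters%s\n",
              cfg$joint, cfg$n_layers, cfg$hidden,
              if (cfg$bidirectional) " (bidirectional)" else " (forward only)",
              n_par, if (is.null(x$loss_history)) " [untrained]" else ""))
  invisible(x)
}

# stack training samples into the (N, C, T) cubes the engine consumes
samples_to_arrays <- function(samples, n_in, n_out) {
  N <- length(samples)
  T_ <- nrow(samples[[1]]$x)
  X <- array(0, c(N, n_in, T_))
  Y <- array(0, c(N, n_out, T_))
  M <- matrix(0, N, T_)
  for (i in seq_len(N)) {
    X[i, , ] <- t(samples[[i]]$x)
    Y[i, , ] <- t(samples[[i]]$y)
    M[i, ] <- samples[[i]]$mask
  }
  list(X = X, Y = Y, M = M, T_ = T_)
}

# per-channel z-scores over valid timesteps only
channel_stats <- function(A, mask) {
  n_valid <- sum(mask)
  mu <- numeric(dim(A)[2]); sd_ <- numeric(dim(A)[2])
  for (c_ in seq_along(mu)) {
    v <- A[, c_, ]               # N x T
    mu[c_] <- sum(v * mask) / n_valid
    sd_[c_] <- sqrt(sum(((v - mu[c_])^2) * mask) / n_valid)
    if (sd_[c_] < 1e-8) sd_[c_] <- 1
  }
  list(mu = mu, sd = sd_)
}

compute_norm <- function(arr) {
  list(x = channel_stats(arr$X, arr$M), y = channel_stats(arr$Y, arr$M))
}

apply_norm <- function(A, M, st) {
  for (c_ in seq_along(st$mu)) {
    A[, c_, ] <- (A[, c_, ] - st$mu[c_]) / st$sd[c_] * M
  }
  A
}

#' Train a BiLSTM model
#'
#' Masked mean-squared-error loss over valid timesteps, Adam optimizer,
#' seeded initialization/shuffling/dropout. Inputs and targets are z-scored
#' per channel with statistics computed from this training set (stored in
#' the model; predictions are mapped back to degrees), since the mixed-unit
#' channels (m/s^2, rad/s, degrees) otherwise destabilize training.
#'
#' @param model a [build_model()] result.
#' @param samples non-empty list of `training_sample`s.
#' @param epochs optional override of the configured epoch count.
#' @return The trained model with `loss_history` (per-epoch mean training
#'   loss in normalized target units).
#' @export
train_bilstm <- function(model, samples, epochs = NULL) {
  if (length(samples) == 0) stop("train_bilstm: empty training set")
  cfg <- model$config
  arr <- samples_to_arrays(samples, model$n_in, model$n_out)
  norm <- compute_norm(arr)
  X <- apply_norm(arr$X, arr$M, norm$x)
  Y <- apply_norm(arr$Y, arr$M, norm$y)
  M <- if (cfg$masked_loss) arr$M else matrix(1, nrow(arr$M), ncol(arr$M))
  fit <- cpp_bilstm_train(model$params, X, Y, M,
                          cfg$n_layers, cfg$hidden,
                          if (cfg$bidirectional) 2L else 1L,
                          epochs %||% cfg$epochs, cfg$batch_size,
                          cfg$lr, cfg$beta1, cfg$beta2, cfg$dropout,
                          cfg$seed)
  model$params <- fit$params
  model$norm <- norm
  model$loss_history <- fit$loss_history
  model
}

#' Predict joint-angle sequences
#'
#' Deterministic evaluation-mode forward pass (dropout disabled). The masked
#' region of the outputs is meaningless and ignored downstream.
#'
#' @param model a trained [bilstm_model].
#' @param samples list of `training_sample`s (their `y` may be zero).
#' @return list of T x n_out predicted angle matrices (degrees).
#' @export
predict_bilstm <- function(model, samples) {
  arr <- samples_to_arrays(samples, model$n_in, model$n_out)
  norm <- model$norm %||% compute_norm(arr)
  X <- apply_norm(arr$X, arr$M, norm$x)
  P <- cpp_bilstm_predict(model$params, X, model$config$n_layers,
                          model$config$hidden,
                          if (model$config$bidirectional) 2L else 1L)
  lapply(seq_len(dim(P)[1]), function(i) {
    y <- t(P[i, , ])                       # T x n_out, normalized units
    sweep(sweep(y, 2, norm$y$sd, "*"), 2, norm$y$mu, "+")
  })
}

#' Subject-wise cross-validation folds
#'
#' @param subjects character vector of training subject ids.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return list of character vectors (validation subjects per fold); every
#'   subject validates exactly once.
#' @export
make_folds <- function(subjects, n_folds = 5, seed = 1) {
  subjects <- unique(as.character(subjects))
  if (length(subjects) < n_folds) {
    stop("make_folds: need at least as many subjects as folds")
  }
  set.seed(seed)
  shuffled <- sample(subjects)
  split(shuffled, rep_len(seq_len(n_folds), length(shuffled)))
}

#' Grid search of (layers, hidden size) by subject-wise cross-validation
#'
#' For each candidate, trains on all but one fold and records the validation
#' RMSE (over valid timesteps, all output DoFs); the candidate with the
#' minimum mean RMSE across folds wins, ties broken toward the smaller
#' parameter count.
#'
#' @param samples list of `training_sample`s (training cohort only).
#' @param grid data frame with columns `n_layers` and `hidden`.
#' @param joint `"hip"` or `"knee"`.
#' @param n_folds fold count.
#' @param epochs training epochs per fold (reduced for tuning).
#' @param seed seed for folds and model init.
#' @param ... further arguments to [bilstm_config()].
#' @return list with `best` (row of `grid`) and `cv_table` (mean/per-fold
#'   validation RMSE per candidate).
#' @export
tune_hyperparameters <- function(samples, grid, joint = "hip", n_folds = 5,
                                 epochs = 10, seed = 1, ...) {
  subjects <- unique(vapply(samples, `[[`, "", "subject"))
  if (length(subjects) < n_folds) {
    stop("tune_hyperparameters: need at least ", n_folds, " training subjects")
  }
  folds <- make_folds(subjects, n_folds, seed)
  subj <- vapply(samples, `[[`, "", "subject")
  results <- matrix(NA_real_, nrow(grid), n_folds)
  for (g in seq_len(nrow(grid))) {
    for (f in seq_len(n_folds)) {
      val <- subj %in% folds[[f]]
      cfg <- bilstm_config(joint, hidden = grid$hidden[g],
                           n_layers = grid$n_layers[g], epochs = epochs,
                           seed = seed, ...)
      model <- train_bilstm(build_model(cfg), samples[!val])
      preds <- predict_bilstm(model, samples[val])
      se <- 0; nv <- 0
      for (i in seq_along(preds)) {
        s <- samples[val][[i]]
        v <- s$mask > 0
        se <- se + sum((preds[[i]][v, ] - s$y[v, ])^2)
        nv <- nv + sum(v) * ncol(s$y)
      }
      results[g, f] <- sqrt(se / nv)
    }
  }
  mean_rmse <- rowMeans(results)
  n_par <- grid$n_layers * grid$hidden   # monotone proxy for model size
  best <- order(mean_rmse, n_par)[1]
  cv <- cbind(grid, mean_rmse = mean_rmse,
              stats::setNames(as.data.frame(results),
                              paste0("fold", seq_len(n_folds))))
  list(best = grid[best, , drop = FALSE], cv_table = cv)
}
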