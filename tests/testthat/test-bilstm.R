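# small synthetic regression task reused across blocks: targets are a fixed
# linear-plus-lag function of the inputs, learnable by a tiny model
make_toy_samples <- function(n = 30, T_ = 40, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    t <- seq_len(T_) / T_
    x <- matrix(0, 200, 24)
    base <- sin(2 * pi * t + stats::runif(1, 0, 2 * pi)) * stats::runif(1, 0.5, 1.5)
    for (c_ in 1:24) x[1:T_, c_] <- base * cos(c_ / 4) + stats::rnorm(T_, 0, 0.01)
    y <- matrix(0, 200, 3)
    y[1:T_, 1] <- 10 * base
    y[1:T_, 2] <- 5 * c(base[-1], base[T_])
    y[1:T_, 3] <- -3 * base
    structure(list(x = x, y = y, mask = c(rep(1, T_), rep(0, 200 - T_)),
                   subject = sprintf("S%02d", (i %% 6) + 1),
                   provenance = "measured_emulated", meta = list()),
              class = "training_sample")
  })
}

test_that("model construction honours the tuned defaults and rejects bad sizes", {
  hip <- build_model(bilstm_config("hip"))
  expect_equal(hip$config$hidden, 32L)
  knee <- build_model(bilstm_config("knee"))
  expect_equal(knee$config$hidden, 128L)
  expect_equal(knee$config$dropout, 0.5)
  expect_equal(knee$config$batch_size, 50L)
  expect_error(bilstm_config("hip", hidden = 0), "positive")
  expect_error(bilstm_config("hip", n_layers = 0), "positive")
  expect_error(bilstm_config("hip", dropout = 1), "dropout")
  # parameter count is the deterministic LSTM + head formula
  H <- 32; D <- 2
  n_expect <- D * (24 * 4 * H + H * 4 * H + 4 * H) +   # lstm
    D * H * H + H + H * 3 + 3                          # head
  expect_equal(sum(vapply(hip$params, length, 0L)), n_expect)
})

test_that("prediction has the contracted shape and is deterministic in eval mode", {
  samples <- make_toy_samples(8)
  model <- build_model(bilstm_config("hip", hidden = 6, seed = 2))
  p1 <- predict_bilstm(model, samples)
  p2 <- predict_bilstm(model, samples)
  expect_length(p1, 8)
  expect_equal(dim(p1[[1]]), c(200, 3))
  expect_identical(p1, p2)
  # duplicated inputs in one batch give identical outputs
  p3 <- predict_bilstm(model, samples[c(1, 1, 1)])
  expect_identical(p3[[1]], p3[[2]])
  expect_identical(p3[[2]], p3[[3]])
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- bilstm_config("hip", hidden = 3, dropout = 0, seed = 3)
  m <- build_model(cfg, n_in = 4, n_out = 2)
  set.seed(4)
  N <- 3; T_ <- 6
  X <- array(stats::rnorm(N * 4 * T_), c(N, 4, T_))
  Y <- array(stats::rnorm(N * 2 * T_), c(N, 2, T_))
  M <- matrix(1, N, T_); M[1, 5:6] <- 0; M[3, 6] <- 0
  lg <- gaitsynth:::cpp_bilstm_loss_grad(m$params, X, Y, M, 1, 3, 2)
  eps <- 1e-6; worst <- 0
  for (pi in seq_along(m$params)) {
    for (j in seq_len(min(4, length(m$params[[pi]])))) {
      pp <- m$params; pp[[pi]][j] <- pp[[pi]][j] + eps
      l1 <- gaitsynth:::cpp_bilstm_loss_grad(pp, X, Y, M, 1, 3, 2)$loss
      pp[[pi]][j] <- pp[[pi]][j] - 2 * eps
      l2 <- gaitsynth:::cpp_bilstm_loss_grad(pp, X, Y, M, 1, 3, 2)$loss
      fd <- (l1 - l2) / (2 * eps)
      an <- lg$grads[[pi]][j]
      worst <- max(worst, abs(fd - an) / max(1e-8, abs(fd) + abs(an)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("padded timesteps contribute no loss and no gradient", {
  cfg <- bilstm_config("hip", hidden = 3, dropout = 0, seed = 3)
  m <- build_model(cfg, n_in = 4, n_out = 2)
  set.seed(5)
  N <- 2; T_ <- 6
  X <- array(stats::rnorm(N * 4 * T_), c(N, 4, T_))
  Y <- array(stats::rnorm(N * 2 * T_), c(N, 2, T_))
  M <- matrix(1, N, T_); M[, 5:6] <- 0
  ref <- gaitsynth:::cpp_bilstm_loss_grad(m$params, X, Y, M, 1, 3, 2)
  Y2 <- Y; Y2[, , 5:6] <- 99          # only masked targets change
  alt <- gaitsynth:::cpp_bilstm_loss_grad(m$params, X, Y2, M, 1, 3, 2)
  expect_identical(ref$loss, alt$loss)
  expect_identical(ref$grads, alt$grads)
})

test_that("training is seeded-deterministic and inert at zero learning rate", {
  samples <- make_toy_samples(12)
  cfg <- bilstm_config("hip", hidden = 5, dropout = 0.3, epochs = 4,
                       batch_size = 6, seed = 11)
  m1 <- train_bilstm(build_model(cfg), samples)
  m2 <- train_bilstm(build_model(cfg), samples)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)

  cfg0 <- bilstm_config("hip", hidden = 5, dropout = 0, epochs = 5,
                        batch_size = 6, lr = 0, seed = 11)
  m0 <- train_bilstm(build_model(cfg0), samples)
  expect_lt(diff(range(m0$loss_history)), 1e-6)
  expect_equal(m0$params, build_model(cfg0)$params, tolerance = 1e-12)
})

test_that("a tiny model memorizes identical noiseless samples to under a degree", {
  one <- make_toy_samples(1, T_ = 50, seed = 21)
  samples <- rep(one, 50)
  cfg <- bilstm_config("knee", hidden = 12, dropout = 0, epochs = 200,
                       batch_size = 50, seed = 1)
  model <- train_bilstm(build_model(cfg), samples)
  pred <- predict_bilstm(model, one)[[1]]
  v <- one[[1]]$mask > 0
  rmse <- sqrt(mean((pred[v, ] - one[[1]]$y[v, ])^2))
  expect_lt(rmse, 1.0)
})

test_that("the model is non-causal: reversing time changes predictions", {
  samples <- make_toy_samples(6, seed = 31)
  cfg <- bilstm_config("hip", hidden = 8, dropout = 0, epochs = 15,
                       batch_size = 6, seed = 7)
  model <- train_bilstm(build_model(cfg), samples)
  rev <- lapply(samples, function(s) {
    n <- sum(s$mask); s$x[1:n, ] <- s$x[n:1, ]; s
  })
  p_fwd <- predict_bilstm(model, samples)
  p_rev <- predict_bilstm(model, rev)
  expect_gt(max(abs(p_fwd[[1]] - p_rev[[1]])), 1e-3)
  # forward-only ablation builds and trains
  cfg1 <- bilstm_config("hip", hidden = 8, dropout = 0, epochs = 2,
                        batch_size = 6, bidirectional = FALSE, seed = 7)
  m1 <- train_bilstm(build_model(cfg1), samples)
  expect_equal(dim(predict_bilstm(m1, samples[1])[[1]]), c(200, 3))
})

test_that("cross-validation folds partition the subjects exactly once", {
  subjects <- sprintf("S%02d", 1:27)
  folds <- make_folds(subjects, 5, seed = 3)
  expect_length(folds, 5)
  expect_setequal(unlist(folds), subjects)
  expect_equal(sum(lengths(folds)), 27)
  expect_true(all(lengths(folds) %in% 5:6))
  expect_error(make_folds(sprintf("S%d", 1:3), 5), "at least")
})

test_that("hyperparameter tuning returns the grid argmin of the emitted CV table", {
  samples <- make_toy_samples(36, seed = 41)
  grid <- data.frame(n_layers = c(1, 1), hidden = c(4, 12))
  tuned <- tune_hyperparameters(samples, grid, joint = "hip", n_folds = 3,
                                epochs = 6, seed = 2, dropout = 0,
                                batch_size = 12)
  expect_equal(nrow(tuned$cv_table), 2)
  best_row <- which(tuned$cv_table$hidden == tuned$best$hidden)
  expect_equal(tuned$cv_table$mean_rmse[best_row],
               min(tuned$cv_table$mean_rmse))
  one <- tune_hyperparameters(samples, data.frame(n_layers = 1, hidden = 4),
                              joint = "hip", n_folds = 3, epochs = 2,
                              seed = 2, dropout = 0, batch_size = 12)
  expect_equal(one$best$hidden, 4)
})
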