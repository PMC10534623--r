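test_that("window normalisation is a translation-invariant round trip", {
  norm <- list(pos_scale = 100, vel_scale = 30)
  ref <- c(50, 5, -20, -3)
  est <- matrix(rep(ref, each = 7), 7, 4)
  meas <- est
  # all rows equal ref with zero velocity -> positions map to zero
  est0 <- est; est0[, c(2, 4)] <- 0
  W0 <- normalize_window(est0, est0, ref, norm)
  expect_equal(W0[, c(1, 3, 5, 7)], matrix(0, 7, 4), ignore_attr = TRUE)
  # round trip
  set.seed(5)
  est <- matrix(stats::rnorm(28, 0, 50), 7, 4)
  meas <- est + matrix(stats::rnorm(28), 7, 4)
  W <- normalize_window(est, meas, ref, norm)
  back_est <- denormalize_state(W[, 1:4], ref, norm)
  back_meas <- denormalize_state(W[, 5:8], ref, norm)
  expect_equal(back_est, est, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back_meas, meas, tolerance = 1e-9, ignore_attr = TRUE)
  # translation invariance
  shift <- c(1000, 0, -500, 0)
  W2 <- normalize_window(sweep(est, 2, shift, `+`),
                         sweep(meas, 2, shift, `+`),
                         ref + shift, norm)
  expect_equal(W2, W, tolerance = 1e-9)
  expect_error(normalize_window(est, meas[1:5, ], ref, norm),
               "differ in length")
})

test_that("windows from a cruising track stay inside the unit box", {
  # pos_scale = v_max * L * delta_t bounds displacements over the window
  L <- 7
  dt <- 1
  v_max <- 30
  norm <- list(pos_scale = v_max * L * dt, vel_scale = v_max)
  tr <- downsample_trajectory(
    generate_trajectory(list(segment_spec("CV", 20, 15,
                                          turn_rate = 0)), 0.1), dt)
  est <- tr$states[1:L, ]
  W <- normalize_window(est, est, est[L, ], norm)
  expect_true(all(abs(W) <= 1))
})

test_that("analytic gradients match finite differences", {
  cfg <- gru_config(num_layers = 2, hidden_dim = 5, window_len = 4,
                    dropout = 0)
  m <- new_gru_model(cfg, list(pos_scale = 10, vel_scale = 5),
                     c(0.1, 1), seed = 3)
  set.seed(9)
  B <- 3
  Xarr <- array(stats::rnorm(B * 4 * 8, sd = 0.5), dim = c(B, 4, 8))
  Tg <- matrix(stats::runif(B * 4, -0.5, 0.5), B, 4)
  bl <- immgru:::batch_loss_grad(m, Xarr, Tg, train = FALSE)
  loss_at <- function(params) {
    m2 <- m
    m2$params <- params
    fw <- immgru:::gru_forward_batch(m2, Xarr, train = FALSE)
    mean((fw$y - Tg)^2)
  }
  eps <- 1e-6
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(bl$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("inference is deterministic and tanh-bounded", {
  cfg <- gru_config(dropout = 0.5)  # dropout must not leak into inference
  m <- new_gru_model(cfg, list(pos_scale = 100, vel_scale = 30),
                     c(0.1, 1), seed = 2)
  set.seed(21)
  est <- matrix(stats::rnorm(28, 0, 30), 7, 4)
  meas <- est + matrix(stats::rnorm(28), 7, 4)
  p1 <- gru_predict(m, est, meas)
  p2 <- gru_predict(m, est, meas)
  expect_identical(p1, p2)
  # normalized head output lies in (-1, 1)^4
  ref <- est[7, ]
  y <- immgru:::normalize_state(p1, ref, m$norm)
  expect_true(all(abs(y) < 1))
  expect_error(gru_predict(m, est[1:5, ], meas[1:5, ]), "window length")
})

test_that("training-set windows are counted and teacher-forced correctly", {
  tr <- generate_trajectory(list(segment_spec("CV", 10, 10)), 0.1)
  expect_equal(length(tr$times), 101L)
  ds <- make_training_set(list(tr), c(1, 1), sim_config(delta_l = 0,
                                                        seed = 1),
                          gru_config(window_len = 7))
  # 11 resampled points, minus the first (undefined velocity) -> 3 windows
  expect_equal(dim(ds$windows)[1], 3L)
  # noiseless: measurement channel equals the truth channel
  expect_equal(ds$windows[, , 5:8], ds$windows[, , 1:4], tolerance = 1e-9)
  # a band sums the per-delta-t window counts over its 0.1 s grid
  tr60 <- generate_trajectory(list(segment_spec("CV", 60, 10)), 0.1)
  n_base <- length(tr60$times)
  ds10 <- make_training_set(list(tr60), c(0.1, 1),
                            sim_config(delta_l = 0, seed = 1),
                            gru_config(window_len = 7))
  per_dt <- vapply(seq(0.1, 1, by = 0.1), function(dt) {
    k <- round(dt / 0.1)
    n <- floor((n_base - 1) / k) + 1
    n - 7 - 1
  }, numeric(1))
  expect_equal(dim(ds10$windows)[1], as.integer(sum(per_dt)))
  # too-short trajectory skipped with a warning
  short <- generate_trajectory(list(segment_spec("CV", 3, 10)), 0.1)
  expect_warning(
    make_training_set(list(short, tr), c(1, 1),
                      sim_config(delta_l = 0, seed = 1),
                      gru_config(window_len = 7)),
    "too short")
})

test_that("a toy dataset can be overfitted and training is reproducible", {
  tr <- generate_trajectory(list(segment_spec("CT", 60, 12,
                                              turn_rate = 0.1)), 0.1)
  ds <- make_training_set(list(tr), c(0.5, 1),
                          sim_config(delta_l = 0.5, seed = 2),
                          gru_config(), max_windows = 32)
  tc <- train_config(batch_size = 32, max_epochs = 200, patience = 200,
                     weight_decay = 0, seed = 1)
  m <- train_model(ds, gru_config(dropout = 0), tc)
  h <- m$history$epochs
  # cosine restarts lift the running loss transiently; judge the best epoch
  expect_lt(min(h$train), 1e-3 * h$train[1])
  # best-validation checkpoint no worse than the starting point
  expect_lte(m$history$best_val, h$val[1])
  # same seed -> identical weights
  m2 <- train_model(ds, gru_config(dropout = 0), tc)
  expect_identical(m$params, m2$params)
})

test_that("a model trained on one regime tracks it almost as well as the
           matched analytic predictor", {
  trajs <- lapply(1:4, function(i) {
    th <- (i - 1) * pi / 3
    generate_trajectory(list(segment_spec("CV", 80, 10 + 2 * i)), 0.1,
                        theta0 = th)
  })
  ds <- make_training_set(trajs, c(1, 1), sim_config(delta_l = 1, seed = 3),
                          gru_config(), max_windows = 1200)
  m <- train_model(ds, gru_config(),
                   train_config(max_epochs = 30, seed = 5))
  held <- downsample_trajectory(
    generate_trajectory(list(segment_spec("CV", 120, 15)), 0.1,
                        theta0 = 1.1), 1)
  fr <- observe_trajectory(held, sim_config(delta_t = 1, delta_l = 1,
                                            p_fa = 0, seed = 44))
  cfg <- tracker_config()
  truth <- held$states[-(1:8), ]
  r_gru <- track(fr, structure(list(m), class = "model_bank"), cfg)
  r_cv <- track(fr, cv_bank(), cfg)
  expect_lte(rmse(r_gru, truth, "prediction"),
             2 * rmse(r_cv, truth, "prediction"))
})

test_that("bank bands tile the sampling-interval range", {
  expect_equal(delta_t_bins(5),
               list(c(0.1, 1), c(1.1, 2), c(2.1, 3), c(3.1, 4), c(4.1, 5)))
  expect_equal(delta_t_bins(1), list(c(0.1, 5)))
  b3 <- delta_t_bins(3)
  expect_equal(b3[[1]][1], 0.1)
  expect_equal(b3[[3]][2], 5)
  for (j in 1:2) {
    expect_equal(b3[[j + 1]][1], b3[[j]][2] + 0.1, tolerance = 1e-9)
  }
})

test_that("checkpoints round-trip through JSON", {
  m <- new_gru_model(gru_config(num_layers = 1, hidden_dim = 4,
                                window_len = 3),
                     list(pos_scale = 10, vel_scale = 5), c(0.1, 1),
                     seed = 8)
  bank <- structure(list(m), class = "model_bank")
  dir <- tempfile()
  save_bank(bank, dir)
  bank2 <- load_bank(dir)
  expect_equal(bank2[[1]]$params, m$params, tolerance = 1e-12)
  expect_equal(bank2[[1]]$norm, m$norm)
  set.seed(1)
  est <- matrix(stats::rnorm(12, 0, 5), 3, 4)
  expect_equal(gru_predict(bank2[[1]], est, est), gru_predict(m, est, est),
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
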