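make_cv_frames <- function(n, T = 1, speed = 12, delta_l = 1, p_fa = 0,
                           seed = 5) {
  tr <- downsample_trajectory(
    generate_trajectory(list(segment_spec("CV", n * T, speed)), 0.1), T)
  list(frames = observe_trajectory(
         tr, sim_config(delta_t = T, delta_l = delta_l, p_fa = p_fa,
                        seed = seed)),
       traj = tr)
}

test_that("warm start fills the window and starts from uniform weights", {
  cfg <- tracker_config()
  sc <- make_cv_frames(30, delta_l = 0)
  st <- init_track(sc$frames, cfg, trained_bank_stub(5))
  expect_equal(st$mu, rep(0.2, 5))
  expect_equal(nrow(st$hist_est[[1]]), cfg$window_len)
  # noiseless CV warm-up converges to the truth
  expect_lt(max(abs(st$est[[1]] - sc$traj$states[8, ])), 1e-6)
  expect_error(init_track(sc$frames[1:4], cfg, trained_bank_stub(5)),
               "warm-up frames")
})

test_that("warm-up filtering beats the raw measurements on noisy data", {
  cfg <- tracker_config()
  err_kf <- err_raw <- numeric(100)
  for (i in 1:100) {
    sc <- make_cv_frames(10, delta_l = 1, seed = 1000 + i)
    st <- init_track(sc$frames, cfg, cv_bank())
    truth <- sc$traj$states[8, c(1, 3)]
    z <- sc$frames[[8]]$points[1, c(1, 3)]
    err_kf[i] <- sum((st$est[[1]][c(1, 3)] - truth)^2)
    err_raw[i] <- sum((z - truth)^2)
  }
  expect_lt(sqrt(mean(err_kf)), sqrt(mean(err_raw)))
})

test_that("mixture density sums its components", {
  cfg <- tracker_config()
  # single component at its mode: 1 / (2 pi sqrt(det))
  pred <- c(10, 1, -5, 0)
  S <- diag(2, 4)
  Sig <- (cfg$H %*% S %*% t(cfg$H) + cfg$R)[c(1, 3), c(1, 3)]
  d <- mixture_density(pred, list(pred), list(S), 1, cfg)
  expect_equal(d, 1 / (2 * pi * sqrt(det(Sig))), tolerance = 1e-12)
  # mirror symmetry of two equal-weight components
  p1 <- c(-10, 0, 0, 0); p2 <- c(10, 0, 0, 0)
  z1 <- c(-12, 0, 1, 0); z2 <- c(12, 0, 1, 0)
  d1 <- mixture_density(z1, list(p1, p2), list(S, S), c(0.5, 0.5), cfg)
  d2 <- mixture_density(z2, list(p1, p2), list(S, S), c(0.5, 0.5), cfg)
  expect_equal(d1, d2, tolerance = 1e-12)
  # three-component mixture equals the brute-force sum
  set.seed(3)
  preds <- lapply(1:3, function(i) stats::rnorm(4, 0, 10))
  covs <- lapply(1:3, function(i) random_psd(4))
  mu <- c(0.2, 0.5, 0.3)
  z <- stats::rnorm(4, 0, 10)
  manual <- sum(vapply(1:3, function(j) {
    Sig <- (covs[[j]] + cfg$R)[c(1, 3), c(1, 3)]
    dv <- z[c(1, 3)] - preds[[j]][c(1, 3)]
    mu[j] * exp(-0.5 * drop(dv %*% solve(Sig) %*% dv)) /
      (2 * pi * sqrt(det(Sig)))
  }, numeric(1)))
  expect_equal(mixture_density(z, preds, covs, mu, cfg), manual,
               tolerance = 1e-9)
})

test_that("measurement selection is density-argmax with index tie-break", {
  cfg <- tracker_config()
  pred <- c(0, 10, 0, 0)
  S <- diag(2, 4)
  fr <- list(time = 1,
             points = rbind(c(0, 10, 0, 0), c(500, 10, 0, 0)),
             truth_index = 1L)
  sel <- select_measurement(fr, list(pred), list(S), 1, cfg)
  expect_equal(sel$index, 1L)
  fr1 <- list(time = 1, points = rbind(c(3, 1, 2, 0)), truth_index = 1L)
  expect_equal(select_measurement(fr1, list(pred), list(S), 1, cfg)$index,
               1L)
  # identical points: lowest index wins
  fr2 <- list(time = 1, points = rbind(c(1, 0, 1, 0), c(1, 0, 1, 0)),
              truth_index = 1L)
  expect_equal(select_measurement(fr2, list(pred), list(S), 1, cfg)$index,
               1L)
})

test_that("the Kalman update matches the textbook form and its limits", {
  set.seed(17)
  for (i in 1:30) {
    S <- random_psd(4)
    pred <- stats::rnorm(4, 0, 10)
    z <- stats::rnorm(4, 0, 10)
    cfg <- tracker_config()
    up <- kalman_update(pred, S, z, cfg)
    G <- S %*% solve(S + cfg$R)
    expect_equal(up$est, drop(pred + G %*% (z - pred)), tolerance = 1e-9)
    Se <- (diag(4) - G) %*% S
    expect_equal(up$S, (Se + t(Se)) / 2, tolerance = 1e-9)
    expect_gte(min(eigen(up$S, symmetric = TRUE)$values), -1e-9)
  }
  # R -> 0: estimate equals the measurement
  cfg0 <- tracker_config(R = diag(1e-12, 4))
  up <- kalman_update(c(0, 0, 0, 0), diag(4), c(1, 2, 3, 4), cfg0)
  expect_equal(up$est, c(1, 2, 3, 4), tolerance = 1e-6)
  # S_pred -> 0: estimate equals the prediction
  up2 <- kalman_update(c(1, 1, 1, 1), diag(1e-14, 4), c(9, 9, 9, 9),
                       tracker_config())
  expect_equal(up2$est, c(1, 1, 1, 1), tolerance = 1e-6)
})

test_that("weight updates follow Bayes' rule with a floor", {
  expect_equal(update_weights(c(0.5, 0.5), c(3, 1)), c(0.75, 0.25))
  expect_equal(update_weights(c(0.3, 0.7), c(2, 2)), c(0.3, 0.7))
  expect_equal(update_weights(1, 5), 1)
  # zero likelihoods leave weights unchanged
  expect_equal(update_weights(c(0.4, 0.6), c(0, 0)), c(0.4, 0.6))
  # floor prevents lock-out and keeps the simplex
  w <- update_weights(c(0.5, 0.5), c(1, 0), floor = 1e-3)
  expect_gte(w[2], 1e-3 / 2)
  expect_equal(sum(w), 1)
})

test_that("prediction combination is the probability-weighted mean", {
  expect_equal(combine_predictions(list(c(1, 2, 3, 4), c(9, 9, 9, 9)),
                                   c(1, 0)), c(1, 2, 3, 4))
  expect_equal(combine_predictions(rbind(c(0, 0, 0, 0), c(2, 2, 2, 2)),
                                   c(0.5, 0.5)), c(1, 1, 1, 1))
  p <- c(4, 3, 2, 1)
  expect_equal(combine_predictions(list(p, p, p), c(0.2, 0.3, 0.5)), p)
})

test_that("with one CV member the loop is exactly a CV Kalman filter", {
  cfg <- tracker_config()
  sc <- make_cv_frames(200, delta_l = 1, seed = 9)
  res <- track(sc$frames, cv_bank(), cfg)
  oracle <- kf_oracle(sc$frames, cfg$Q, cfg$R, 1)
  expect_lt(max(abs(res$est - oracle[-(1:7), ])), 1e-9)
  # single-model weight trace is constant 1
  expect_true(all(res$mu == 1))
})

test_that("weights stay on the simplex and covariances stay PSD", {
  cfg <- tracker_config()
  tr <- downsample_trajectory(piecewise_scenario(21, duration = 60), 2)
  fr <- observe_trajectory(tr, sim_config(delta_t = 2, delta_l = 1,
                                          p_fa = 0.1, seed = 8))
  bank <- trained_bank_stub(3)
  st <- init_track(fr, cfg, bank)
  for (k in 9:length(fr)) {
    out <- track_step(st, fr[[k]], bank, cfg)
    st <- out$state
    expect_equal(sum(st$mu), 1, tolerance = 1e-9)
    expect_true(all(st$mu >= 0))
    for (j in seq_len(st$n)) {
      expect_equal(st$S[[j]], t(st$S[[j]]), tolerance = 1e-9)
      expect_gte(min(eigen(st$S[[j]], symmetric = TRUE)$values), -1e-9)
    }
  }
})

test_that("far-off false alarms are rejected by the gate", {
  # false point placed 10 innovation sigmas from the prediction
  cfg <- tracker_config()
  sc <- make_cv_frames(500, delta_l = 1, seed = 23)
  frames <- sc$frames
  sigma <- sqrt(4 + 16 + 4)  # rough innovation scale per axis
  set.seed(77)
  for (k in 9:length(frames)) {
    ang <- stats::runif(1, 0, 2 * pi)
    off <- 10 * sigma * c(cos(ang), sin(ang))
    fa <- frames[[k]]$points[1, ] + c(off[1], 0, off[2], 0)
    frames[[k]]$points <- rbind(fa, frames[[k]]$points[1, ])
    frames[[k]]$truth_index <- 2L
  }
  res <- track(frames, cv_bank(), cfg)
  expect_gte(mean(res$chosen == res$truth_index), 0.99)
})
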