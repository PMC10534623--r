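# Shared fixtures. Heavy objects (the trained model bank) are built once per
# test run and cached; every fixture is generated in code from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# Training trajectories for the desk-scale bank: eight pigeon-like
# piecewise tracks of ~150 s each at 0.1 s base sampling.
training_trajectories <- function() {
  memo("train_trajs", function() {
    lapply(1:8, function(i) piecewise_scenario(211L + i, duration = 150))
  })
}

# Desk-scale 5-model bank: protocol architecture (2 bidirectional layers,
# 32 hidden units, L = 7, dropout 0.1), up to 3000 windows per band and a
# 150-epoch cap under 20-epoch patience. Trained once per test run.
trained_bank <- function() {
  memo("bank5", function() {
    build_bank(training_trajectories(), 5,
               gru_config(),
               train_config(max_epochs = 150L, seed = 41L),
               sim_config(delta_l = 1, seed = 7L),
               max_windows_per_bin = 3000L)
  })
}

cv_bank <- function() {
  structure(list(cv_predictor()), class = "model_bank")
}

# Cheap analytic n-member bank for tests of the multi-model machinery that
# do not need trained networks.
trained_bank_stub <- function(n) {
  structure(rep(list(cv_predictor()), n), class = "model_bank")
}

# Textbook CV Kalman filter over single-point frames, starting from the
# first point with covariance R. Returns the posterior trace from frame 2.
kf_oracle <- function(frames, Q, R, T) {
  F <- cv_matrix(T)
  x <- frames[[1]]$points[1, ]
  S <- R
  est <- matrix(0, length(frames) - 1, 4)
  for (k in 2:length(frames)) {
    pred <- drop(F %*% x)
    Sp <- F %*% S %*% t(F) + Q
    z <- frames[[k]]$points[1, ]
    G <- Sp %*% solve(Sp + R)
    x <- drop(pred + G %*% (z - pred))
    S <- (diag(4) - G %*% diag(4)) %*% Sp
    est[k - 1, ] <- x
  }
  est
}

random_psd <- function(n) {
  A <- matrix(stats::rnorm(n * n), n, n)
  crossprod(A) + diag(0.1, n)
}
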