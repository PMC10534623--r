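# Classical reference trackers. All share the simple argmax-density gate
# (no back-tracking), consume the same warm-up frames as the main tracker,
# and emit the same track_result container so metrics are comparable.

#' Baseline tracker configuration
#'
#' @param method One of `"UKF"`, `"IMM_UKF"`, `"PF"`, `"GRU_EKF"`.
#' @param n_particles Particle count for the PF.
#' @param ukf_alpha,ukf_beta,ukf_kappa Sigma-point spread parameters.
#' @param q_omega Process-noise variance of the augmented turn-rate state
#'   (UKF) per step.
#' @param omega_init,omega_init_var Initial turn rate and its variance for
#'   the augmented UKF state.
#' @param imm_omegas Fixed turn rates (rad/s) of the IMM-UKF member models;
#'   0 is the CV member. These are free parameters of the comparison, not
#'   canonical values.
#' @param imm_self_transition Self-transition probability of the IMM Markov
#'   chain (off-diagonal mass spread uniformly).
#' @param pf_sigma_omega Random-walk standard deviation of the PF turn-rate
#'   state per unit sqrt-time.
#' @param seed Seed for the PF.
#' @return A list of class `"baseline_config"`.
#' @export
baseline_config <- function(method = c("UKF", "IMM_UKF", "PF", "GRU_EKF"),
                            n_particles = 1000L,
                            ukf_alpha = 1e-3, ukf_beta = 2, ukf_kappa = 0,
                            q_omega = 1e-4,
                            omega_init = 0, omega_init_var = 0.01,
                            imm_omegas = c(0, 0.2, -0.2),
                            imm_self_transition = 0.9,
                            pf_sigma_omega = 0.05,
                            seed = 1L) {
  method <- match.arg(method)
  stopifnot(n_particles >= 1, imm_self_transition > 0,
            imm_self_transition <= 1)
  structure(list(method = method, n_particles = as.integer(n_particles),
                 ukf_alpha = ukf_alpha, ukf_beta = ukf_beta,
                 ukf_kappa = ukf_kappa, q_omega = q_omega,
                 omega_init = omega_init, omega_init_var = omega_init_var,
                 imm_omegas = imm_omegas,
                 imm_self_transition = imm_self_transition,
                 pf_sigma_omega = pf_sigma_omega,
                 seed = as.integer(seed)),
            class = "baseline_config")
}

# Symmetric PSD matrix square root (eigen-based; tolerates zero eigenvalues,
# unlike Cholesky).
psd_sqrt <- function(P) {
  e <- eigen((P + t(P)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(P)) %*% t(e$vectors)
}

ukf_weights <- function(n, alpha, beta, kappa) {
  lambda <- alpha^2 * (n + kappa) - n
  wm <- c(lambda / (n + lambda), rep(1 / (2 * (n + lambda)), 2 * n))
  wc <- wm
  wc[1] <- wc[1] + (1 - alpha^2 + beta)
  list(lambda = lambda, wm = wm, wc = wc)
}

ukf_sigma_points <- function(x, P, lambda) {
  n <- length(x)
  A <- psd_sqrt((n + lambda) * P)
  cbind(x, x + A, x - A)
}

# Unscented prediction through the coordinated-turn dynamics. For the
# augmented model the 5th state component is the turn rate (random walk);
# for a fixed-rate model the state stays 4-D and the dynamics are linear.
ukf_predict <- function(x, P, T, Q, bcfg, model) {
  if (model$type == "fixed") {
    F <- ct_matrix(T, model$omega)
    xp <- drop(F %*% x)
    Pp <- propagate_covariance(F, P, Q)
    return(list(x = xp, P = Pp))
  }
  n <- length(x)
  w <- ukf_weights(n, bcfg$ukf_alpha, bcfg$ukf_beta, bcfg$ukf_kappa)
  chi <- ukf_sigma_points(x, P, w$lambda)
  prop <- apply(chi, 2, function(s) {
    c(drop(ct_matrix(T, s[5]) %*% s[1:4]), s[5])
  })
  xp <- drop(prop %*% w$wm)
  dev <- prop - xp
  Pp <- dev %*% (w$wc * t(dev))
  Q5 <- rbind(cbind(Q, 0), c(rep(0, 4), bcfg$q_omega * T))
  Pp <- (Pp + t(Pp)) / 2 + Q5
  list(x = xp, P = Pp)
}

# Linear measurement update (the measurement model is linear, so the
# unscented transform is unnecessary and the exact Kalman form is used).
ukf_update <- function(x, P, z, cfg) {
  n <- length(x)
  H <- cbind(cfg$H, matrix(0, 4, n - 4))
  Sz <- H %*% P %*% t(H) + cfg$R
  K <- P %*% t(H) %*% solve(Sz)
  est <- drop(x + K %*% (z - drop(H %*% x)))
  Pn <- (diag(n) - K %*% H) %*% P
  list(x = est, P = (Pn + t(Pn)) / 2, Sz = Sz, z_pred = drop(H %*% x))
}

# Argmax-density gate shared by the baselines: pick the candidate point
# with the highest Gaussian density under the predicted measurement.
baseline_gate <- function(frame, z_pred, Sz, cfg) {
  idx <- gate_index(cfg)
  dens <- vapply(seq_len(nrow(frame$points)), function(i) {
    gaussian_density(frame$points[i, idx], z_pred[idx],
                     Sz[idx, idx, drop = FALSE])
  }, numeric(1))
  i <- which.max(dens)
  list(index = i, z = frame$points[i, ], density = dens[i])
}

baseline_record <- function(frame, pred4, est4, mu, gate) {
  list(time = frame$time, pred = pred4, est = est4, mu = mu,
       chosen = as.integer(gate$index), density = gate$density,
       truth_index = as.integer(frame$truth_index),
       n_points = as.integer(nrow(frame$points)))
}

#' Unscented Kalman filter baseline
#'
#' Coordinated-turn dynamics with an augmented turn-rate state
#' `[x, vx, y, vy, omega]`; the turn rate follows a random walk with
#' per-step variance `q_omega * T`. The first frame initialises the state;
#' recording starts after the same warm-up span as the main tracker.
#'
#' @param frames List of scan frames.
#' @param cfg A [tracker_config()].
#' @param bcfg A [baseline_config()].
#' @return A `"track_result"`.
#' @export
run_ukf <- function(frames, cfg = tracker_config(),
                    bcfg = baseline_config("UKF")) {
  model <- list(type = "augmented")
  x <- c(frames[[1]]$points[1, ], bcfg$omega_init)
  P <- rbind(cbind(cfg$R, 0), c(rep(0, 4), bcfg$omega_init_var))
  warmup <- cfg$window_len + 1L
  records <- list()
  for (k in 2:length(frames)) {
    T <- frames[[k]]$time - frames[[k - 1]]$time
    pr <- ukf_predict(x, P, T, cfg$Q, bcfg, model)
    H <- cbind(cfg$H, matrix(0, 4, length(x) - 4))
    Sz <- H %*% pr$P %*% t(H) + cfg$R
    gate <- baseline_gate(frames[[k]], drop(H %*% pr$x), Sz, cfg)
    up <- ukf_update(pr$x, pr$P, gate$z, cfg)
    x <- up$x
    P <- up$P
    if (k > warmup) {
      records[[length(records) + 1L]] <-
        baseline_record(frames[[k]], pr$x[1:4], x[1:4], 1, gate)
    }
  }
  build_track_result(records, n_models = 1L, warmup = warmup)
}

#' Interacting-multiple-model UKF baseline
#'
#' Standard IMM over a fixed set of coordinated-turn members (default
#' `{CV, CT(+0.2), CT(-0.2)}`): probability mixing with a Markov transition
#' matrix, per-member unscented prediction and Kalman update, and
#' likelihood-weighted combination.
#'
#' @inheritParams run_ukf
#' @return A `"track_result"` with per-member weights.
#' @export
run_imm_ukf <- function(frames, cfg = tracker_config(),
                        bcfg = baseline_config("IMM_UKF")) {
  omegas <- bcfg$imm_omegas
  n <- length(omegas)
  if (n == 1L) {
    # one member degenerates to the plain augmented UKF
    return(run_ukf(frames, cfg, bcfg))
  }
  p_self <- bcfg$imm_self_transition
  Pi <- matrix((1 - p_self) / (n - 1), n, n)
  diag(Pi) <- p_self
  models <- lapply(omegas, function(w) list(type = "fixed", omega = w))
  z1 <- frames[[1]]$points[1, ]
  xs <- rep(list(z1), n)
  Ps <- rep(list(cfg$R), n)
  mu <- rep(1 / n, n)
  warmup <- cfg$window_len + 1L
  records <- list()
  idx <- gate_index(cfg)
  for (k in 2:length(frames)) {
    T <- frames[[k]]$time - frames[[k - 1]]$time
    # interaction / mixing
    cj <- drop(mu %*% Pi)
    cj[cj < 1e-300] <- 1e-300
    x0 <- vector("list", n)
    P0 <- vector("list", n)
    for (j in seq_len(n)) {
      wij <- Pi[, j] * mu / cj[j]
      xm <- Reduce(`+`, Map(function(w, x) w * x, wij, xs))
      Pm <- Reduce(`+`, Map(function(w, x, P) {
        w * (P + tcrossprod(x - xm))
      }, wij, xs, Ps))
      x0[[j]] <- xm
      P0[[j]] <- (Pm + t(Pm)) / 2
    }
    # per-member prediction
    prs <- Map(function(x, P, mdl) ukf_predict(x, P, T, cfg$Q, bcfg, mdl),
               x0, P0, models)
    preds <- lapply(prs, `[[`, "x")
    S_preds <- lapply(prs, `[[`, "P")
    # gate on the predictive mixture
    sel <- select_measurement(frames[[k]], preds, S_preds, cj, cfg)
    # per-member update and likelihood
    lik <- numeric(n)
    for (j in seq_len(n)) {
      up <- ukf_update(preds[[j]], S_preds[[j]], sel$z, cfg)
      lik[j] <- gaussian_density(sel$z[idx], up$z_pred[idx],
                                 up$Sz[idx, idx, drop = FALSE])
      xs[[j]] <- up$x
      Ps[[j]] <- up$P
    }
    mu <- update_weights(cj, lik, 0)
    comb_pred <- combine_predictions(preds, cj)
    comb_est <- combine_predictions(xs, mu)
    if (k > warmup) {
      records[[length(records) + 1L]] <- baseline_record(
        frames[[k]], comb_pred, comb_est, mu,
        list(index = sel$index, density = sel$density))
    }
  }
  build_track_result(records, n_models = n, warmup = warmup)
}

#' Bootstrap particle filter baseline
#'
#' Coordinated-turn dynamics with a random-walk turn-rate state, Gaussian
#' measurement likelihood with covariance `R`, and systematic resampling
#' when the effective sample size drops below half the particle count. The
#' estimate is the weighted particle mean. Fully seeded.
#'
#' @inheritParams run_ukf
#' @return A `"track_result"`.
#' @export
run_pf <- function(frames, cfg = tracker_config(),
                   bcfg = baseline_config("PF")) {
  np <- bcfg$n_particles
  warmup <- cfg$window_len + 1L
  chQ <- psd_sqrt(cfg$Q)
  chR <- diag(cfg$R)
  records <- list()
  with_seed(bcfg$seed, {
    z1 <- frames[[1]]$points[1, ]
    X <- cbind(matrix(rep(z1, each = np), np, 4) +
                 matrix(stats::rnorm(np * 4), np, 4) %*% chQ * 0.25,
               stats::rnorm(np, bcfg$omega_init,
                            sqrt(bcfg$omega_init_var)))
    w <- rep(1 / np, np)
    for (k in 2:length(frames)) {
      T <- frames[[k]]$time - frames[[k - 1]]$time
      # propagate: elementwise coordinated-turn closed form per particle
      wv <- X[, 5]
      small <- abs(wv) < 1e-8
      s <- sin(wv * T)
      cc <- cos(wv * T)
      sw <- ifelse(small, T, s / wv)
      cw <- ifelse(small, 0.5 * wv * T^2, (1 - cc) / wv)
      Xn <- X
      Xn[, 1] <- X[, 1] + X[, 2] * sw - X[, 4] * cw
      Xn[, 2] <- X[, 2] * cc - X[, 4] * s
      Xn[, 3] <- X[, 3] + X[, 2] * cw + X[, 4] * sw
      Xn[, 4] <- X[, 2] * s + X[, 4] * cc
      Xn[, 1:4] <- Xn[, 1:4] + matrix(stats::rnorm(np * 4), np, 4) %*% chQ
      Xn[, 5] <- Xn[, 5] + stats::rnorm(np, 0,
                                        bcfg$pf_sigma_omega * sqrt(T))
      X <- Xn
      pred_mean <- drop(w %*% X[, 1:4])
      pred_cov <- stats::cov.wt(X[, 1:4], wt = w, method = "ML")$cov
      gate <- baseline_gate(frames[[k]], pred_mean, pred_cov + cfg$R, cfg)
      z <- gate$z
      # weight by the 4-D measurement likelihood (independent components)
      log_lik <- -0.5 * colSums((t(X[, 1:4]) - z)^2 / chR) -
        0.5 * sum(log(2 * pi * chR))
      lw <- log(w) + log_lik
      lw <- lw - max(lw)
      w <- exp(lw)
      sw <- sum(w)
      if (!is.finite(sw) || sw <= 0) {
        # degeneracy: reinitialise around the last gated measurement
        X[, 1:4] <- matrix(rep(z, each = np), np, 4) +
          matrix(stats::rnorm(np * 4), np, 4) %*% psd_sqrt(cfg$R)
        w <- rep(1 / np, np)
      } else {
        w <- w / sw
      }
      est <- drop(w %*% X[, 1:4])
      if (1 / sum(w^2) < np / 2) {
        # systematic resampling
        u <- (stats::runif(1) + 0:(np - 1)) / np
        idx <- findInterval(u, cumsum(w)) + 1L
        idx[idx > np] <- np
        X <- X[idx, , drop = FALSE]
        w <- rep(1 / np, np)
      }
      if (k > warmup) {
        records[[length(records) + 1L]] <-
          baseline_record(frames[[k]], pred_mean, est, 1, gate)
      }
    }
  })
  build_track_result(records, n_models = 1L, warmup = warmup)
}

#' Single-model GRU-EKF baseline
#'
#' The same loop as the IMM-GRU tracker with a bank of one (typically
#' larger) recurrent model: with a single member the probability update is
#' vacuous and the loop is a GRU-predicted Kalman filter.
#'
#' @param frames List of scan frames.
#' @param big_model A `"gru_motion_model"` trained on the whole 0.1-5 s
#'   sampling-interval range.
#' @param cfg A [tracker_config()].
#' @return A `"track_result"`.
#' @export
run_gru_ekf <- function(frames, big_model, cfg = tracker_config()) {
  track(frames, structure(list(big_model), class = "model_bank"), cfg)
}
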