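# The IMM-GRU tracking loop.
#
# Each cycle: (1) every bank member predicts the next state from the shared
# measurement history and its own estimate history; (2) each prediction is
# converted to an approximate linear transition (fitted CV/CT blend) so the
# per-model covariance can be propagated; (3) the scan's candidate points
# are gated by the mixture-Gaussian predictive density and the most probable
# point is taken as the measurement; (4) each model runs a Kalman update;
# (5) model probabilities are updated by Bayes' rule from the per-model
# predictive likelihood of the selected measurement; (6) the combined
# estimate/prediction is the probability-weighted mean.

#' Tracker configuration
#'
#' @param Q 4x4 process-noise covariance. The default `16 I` deliberately
#'   under-trusts the transition so the filter re-converges quickly after a
#'   motion change.
#' @param R 4x4 measurement-noise covariance; default `4 I`, matching a
#'   sensor with ~1 m range resolution (position noise variance 4 m^2).
#' @param H 4x4 measurement matrix; identity, since the measurement is the
#'   full `[x, vx, y, vy]` with velocity observed by position differencing.
#' @param mu_floor Lower clamp on model probabilities (then renormalised);
#'   prevents irrecoverable model lock-out. Set 0 to allow full Bayes
#'   saturation.
#' @param window_len History window length L fed to the motion models.
#' @param gate_full If `TRUE`, gating and likelihood densities are evaluated
#'   on the full 4-D measurement; default `FALSE` uses the 2-D position
#'   marginal (differenced velocities double-count the position noise).
#' @return A list of class `"tracker_config"`.
#' @export
tracker_config <- function(Q = diag(16, 4), R = diag(4, 4), H = diag(4),
                           mu_floor = 1e-3, window_len = 7L,
                           gate_full = FALSE) {
  stopifnot(mu_floor >= 0, mu_floor <= 0.1, window_len >= 2)
  structure(list(Q = Q, R = R, H = H, mu_floor = mu_floor,
                 window_len = as.integer(window_len),
                 gate_full = gate_full),
            class = "tracker_config")
}

# Multivariate normal density with ridge regularisation of a singular
# covariance (1e-9 I), used for gating and model likelihoods.
gaussian_density <- function(z, mean, Sigma) {
  d <- length(z)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- chol(Sigma + diag(1e-9, d))
  }
  diff <- backsolve(ch, z - mean, transpose = TRUE)
  exp(-0.5 * sum(diff^2)) / ((2 * pi)^(d / 2) * prod(diag(ch)))
}

gate_index <- function(cfg) if (isTRUE(cfg$gate_full)) 1:4 else c(1, 3)

# Predictive density of measurement z under model j:
# N(z; H x_pred, H S_pred H' + R), marginalised per cfg$gate_full.
component_density <- function(z, pred, S_pred, cfg) {
  idx <- gate_index(cfg)
  mean_z <- drop(cfg$H %*% pred)
  Sigma <- cfg$H %*% S_pred %*% t(cfg$H) + cfg$R
  gaussian_density(z[idx], mean_z[idx], Sigma[idx, idx, drop = FALSE])
}

#' Mixture-Gaussian predictive density of a candidate point
#'
#' Evaluates `sum_j mu_j N(z; H x_pred_j, H S_pred_j H' + R)` on the
#' position marginal (or the full 4-D measurement when the configuration
#' requests it). This is the density used both to gate candidate scan
#' points and to score back-tracking hypotheses.
#'
#' @param z Candidate measurement `[x, vx, y, vy]`.
#' @param predictions List (or n x 4 matrix) of per-model predicted states.
#' @param covs List of per-model predicted covariances.
#' @param weights Model probabilities (sum to 1).
#' @param cfg A [tracker_config()].
#' @return A non-negative density (units m^-2 for the position marginal).
#' @export
mixture_density <- function(z, predictions, covs, weights, cfg) {
  if (is.matrix(predictions)) {
    predictions <- lapply(seq_len(nrow(predictions)),
                          function(j) predictions[j, ])
  }
  dens <- 0
  for (j in seq_along(weights)) {
    dens <- dens + weights[j] *
      component_density(z, predictions[[j]], covs[[j]], cfg)
  }
  dens
}

#' Select the most probable measurement in a scan
#'
#' Returns the candidate point with the largest mixture-Gaussian predictive
#' density; ties break to the lowest point index.
#'
#' @param frame A scan frame (list with `points`, `time`, `truth_index`).
#' @param predictions,covs,weights Per-model predicted states, covariances
#'   and probabilities.
#' @param cfg A [tracker_config()].
#' @return A list with `index`, `z` (the chosen 4-vector) and `density`.
#' @export
select_measurement <- function(frame, predictions, covs, weights, cfg) {
  d <- nrow(frame$points)
  if (d == 0L) {
    return(list(index = NA_integer_, z = NULL, density = NA_real_))
  }
  dens <- vapply(seq_len(d), function(i) {
    mixture_density(frame$points[i, ], predictions, covs, weights, cfg)
  }, numeric(1))
  i <- which.max(dens)
  list(index = i, z = frame$points[i, ], density = dens[i])
}

#' Kalman measurement update
#'
#' Standard update with gain `G = S H' (H S H' + R)^-1`; the posterior
#' covariance is symmetrised. A numerically singular innovation covariance
#' is ridge-regularised.
#'
#' @param pred Predicted state.
#' @param S_pred Predicted covariance (PSD).
#' @param z Measurement 4-vector.
#' @param cfg A [tracker_config()].
#' @return List with `est` and `S`.
#' @export
kalman_update <- function(pred, S_pred, z, cfg) {
  H <- cfg$H
  Sz <- H %*% S_pred %*% t(H) + cfg$R
  G <- tryCatch(S_pred %*% t(H) %*% solve(Sz),
                error = function(e) {
                  S_pred %*% t(H) %*% solve(Sz + diag(1e-9, nrow(Sz)))
                })
  est <- drop(pred + G %*% (z - drop(H %*% pred)))
  S <- (diag(nrow(S_pred)) - G %*% H) %*% S_pred
  list(est = est, S = (S + t(S)) / 2)
}

#' Bayesian model-probability update
#'
#' `mu_j' \propto likelihood_j * mu_j`, renormalised, then clamped below by
#' `floor` and renormalised again. If every likelihood is zero the weights
#' are left unchanged.
#'
#' @param mu Current model probabilities (sum to 1).
#' @param likelihoods Per-model predictive likelihoods (>= 0).
#' @param floor Probability floor in `[0, 0.1]`.
#' @return Updated probabilities on the simplex.
#' @export
update_weights <- function(mu, likelihoods, floor = 0) {
  w <- mu * likelihoods
  s <- sum(w)
  if (!is.finite(s) || s <= 0) {
    return(mu)
  }
  w <- w / s
  if (floor > 0) {
    w <- pmax(w, floor)
    w <- w / sum(w)
  }
  w
}

#' Probability-weighted combination of per-model predictions
#'
#' @param preds List (or n x 4 matrix) of per-model states.
#' @param mu Model probabilities (sum to 1).
#' @return The weighted mean state.
#' @export
combine_predictions <- function(preds, mu) {
  if (is.list(preds)) preds <- do.call(rbind, preds)
  drop(crossprod(preds, mu))
}

#' Initialise the tracker from the first warm-up scans
#'
#' Runs a constant-velocity Kalman filter over the first `L + 1` frames to
#' fill the history window the motion models require. Warm-up frames are
#' expected to be single-point; if a frame holds several candidates the one
#' nearest the running prediction is taken. Model probabilities start
#' uniform; the warm-up filter starts from covariance `R` and every
#' per-model covariance continues from its final posterior, so a bank of
#' one analytic CV predictor continues the warm-up filter seamlessly.
#'
#' @param frames List of at least `L + 1` scan frames.
#' @param cfg A [tracker_config()].
#' @param bank A model bank (its length sets the number of models).
#' @return A list of class `"tracker_state"`.
#' @export
init_track <- function(frames, cfg, bank) {
  L <- cfg$window_len
  if (length(frames) < L + 1) {
    stop(sprintf("init_track: need at least %d warm-up frames, got %d",
                 L + 1, length(frames)), call. = FALSE)
  }
  frames <- frames[seq_len(L + 1)]
  T <- frames[[2]]$time - frames[[1]]$time
  F <- cv_matrix(T)
  pick <- function(fr, ref_pos) {
    if (nrow(fr$points) == 1L || is.null(ref_pos)) {
      return(fr$points[1, ])
    }
    d2 <- (fr$points[, 1] - ref_pos[1])^2 + (fr$points[, 3] - ref_pos[2])^2
    fr$points[which.min(d2), ]
  }
  z <- pick(frames[[1]], NULL)
  x <- z
  S <- cfg$R
  est_hist <- matrix(0, L, 4)
  meas_hist <- matrix(0, L, 4)
  for (k in 2:(L + 1)) {
    pred <- drop(F %*% x)
    S_pred <- propagate_covariance(F, S, cfg$Q)
    z <- pick(frames[[k]], pred[c(1, 3)])
    up <- kalman_update(pred, S_pred, z, cfg)
    x <- up$est
    S <- up$S
    est_hist[k - 1, ] <- x
    meas_hist[k - 1, ] <- z
  }
  n <- length(bank)
  structure(list(
    time = frames[[L + 1]]$time,
    T = T,
    n = n,
    est = rep(list(x), n),
    S = rep(list(S), n),
    mu = rep(1 / n, n),
    hist_est = rep(list(est_hist), n),
    hist_meas = meas_hist
  ), class = "tracker_state")
}

#' Advance the tracker by one scan
#'
#' Executes one full cycle (prediction, covariance propagation, gating,
#' Kalman update, probability update, combination) and returns the new
#' state plus a per-step record. An empty frame carries the combined
#' prediction forward as a pseudo-measurement under a 10x inflated `R`.
#'
#' @param state A `"tracker_state"`.
#' @param frame The next scan frame.
#' @param bank The model bank.
#' @param cfg A [tracker_config()].
#' @param forced_index Optional candidate index to associate instead of the
#'   gate's argmax (used by the back-tracking beam).
#' @return List with the advanced `state` and a `record` (combined
#'   prediction/estimate, weights, chosen point, gate density, per-model
#'   predictions).
#' @export
track_step <- function(state, frame, bank, cfg, forced_index = NULL) {
  n <- state$n
  L <- cfg$window_len
  T <- frame$time - state$time

  preds <- vector("list", n)
  S_preds <- vector("list", n)
  for (j in seq_len(n)) {
    hist <- state$hist_est[[j]]
    preds[[j]] <- predict_next(bank[[j]], hist, state$hist_meas, T)
    omega <- estimate_turn_rate(hist[L - 1, ], hist[L, ], T)
    Fj <- approx_transfer(state$est[[j]], preds[[j]], T, omega)
    S_preds[[j]] <- propagate_covariance(Fj, state$S[[j]], cfg$Q)
  }

  if (nrow(frame$points) == 0L) {
    comb_pred <- combine_predictions(preds, state$mu)
    z <- comb_pred
    chosen <- NA_integer_
    density <- NA_real_
    R_eff <- cfg$R * 10
    cfg_eff <- cfg
    cfg_eff$R <- R_eff
  } else if (!is.null(forced_index)) {
    chosen <- forced_index
    z <- frame$points[forced_index, ]
    density <- mixture_density(z, preds, S_preds, state$mu, cfg)
    cfg_eff <- cfg
  } else {
    sel <- select_measurement(frame, preds, S_preds, state$mu, cfg)
    chosen <- sel$index
    z <- sel$z
    density <- sel$density
    cfg_eff <- cfg
  }

  ests <- vector("list", n)
  Ss <- vector("list", n)
  lik <- numeric(n)
  for (j in seq_len(n)) {
    up <- kalman_update(preds[[j]], S_preds[[j]], z, cfg_eff)
    ests[[j]] <- up$est
    Ss[[j]] <- up$S
    lik[j] <- component_density(z, preds[[j]], S_preds[[j]], cfg_eff)
  }
  mu <- update_weights(state$mu, lik, cfg$mu_floor)

  comb_est <- combine_predictions(ests, mu)
  comb_pred <- combine_predictions(preds, mu)

  hist_est <- vector("list", n)
  for (j in seq_len(n)) {
    hist_est[[j]] <- rbind(state$hist_est[[j]][-1, , drop = FALSE],
                           ests[[j]])
  }
  hist_meas <- rbind(state$hist_meas[-1, , drop = FALSE], z)

  new_state <- structure(list(
    time = frame$time, T = T, n = n,
    est = ests, S = Ss, mu = mu,
    hist_est = hist_est, hist_meas = hist_meas
  ), class = "tracker_state")

  record <- list(time = frame$time, pred = comb_pred, est = comb_est,
                 mu = mu, chosen = as.integer(chosen), density = density,
                 truth_index = as.integer(frame$truth_index),
                 n_points = as.integer(nrow(frame$points)))
  list(state = new_state, record = record)
}

#' Track a full scan sequence
#'
#' Warm-starts on the first `L + 1` frames ([init_track()]) and then steps
#' through the rest.
#'
#' @param frames List of scan frames (e.g. from [observe_trajectory()]).
#' @param bank The model bank.
#' @param cfg A [tracker_config()].
#' @return A `"track_result"`: per-step matrices `pred`, `est`, `mu`,
#'   vectors `time`, `chosen`, `density`, false-alarm bookkeeping and the
#'   number of warm-up frames consumed.
#' @export
track <- function(frames, bank, cfg = tracker_config()) {
  L <- cfg$window_len
  state <- init_track(frames, cfg, bank)
  steps <- frames[-(seq_len(L + 1))]
  records <- vector("list", length(steps))
  for (k in seq_along(steps)) {
    out <- track_step(state, steps[[k]], bank, cfg)
    state <- out$state
    records[[k]] <- out$record
  }
  build_track_result(records, n_models = state$n, warmup = L + 1)
}

build_track_result <- function(records, n_models, warmup) {
  m <- length(records)
  res <- list(
    time = vapply(records, `[[`, numeric(1), "time"),
    pred = t(vapply(records, `[[`, numeric(4), "pred")),
    est = t(vapply(records, `[[`, numeric(4), "est")),
    mu = t(vapply(records, `[[`, numeric(n_models), "mu")),
    chosen = vapply(records, `[[`, integer(1), "chosen"),
    density = vapply(records, `[[`, numeric(1), "density"),
    truth_index = vapply(records, `[[`, integer(1), "truth_index"),
    n_points = vapply(records, `[[`, integer(1), "n_points"),
    warmup = warmup
  )
  if (n_models == 1L) res$mu <- matrix(res$mu, ncol = 1L)
  had_fa <- res$n_points > 1L & res$truth_index > 0L
  res$n_false_present <- sum(had_fa)
  res$n_false_selected <- sum(had_fa & res$chosen != res$truth_index,
                              na.rm = TRUE)
  structure(res, class = "track_result")
}

#' Write a track result as CSV
#'
#' One row per tracked step: `t, x_pred, y_pred, x_est, y_est, mu_1..mu_n,
#' chosen_point_id, gate_density`.
#'
#' @param result A `"track_result"`.
#' @param path File path.
#' @export
write_track_csv <- function(result, path) {
  mu <- result$mu
  colnames(mu) <- paste0("mu_", seq_len(ncol(mu)))
  df <- data.frame(t = result$time,
                   x_pred = result$pred[, 1], y_pred = result$pred[, 3],
                   x_est = result$est[, 1], y_est = result$est[, 3],
                   mu,
                   chosen_point_id = result$chosen,
                   gate_density = result$density)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
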