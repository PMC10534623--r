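# Linear kinematic transition matrices and the approximate one-step
# state-transfer matrix: a convex blend alpha*F_CV + (1-alpha)*F_CT fitted so
# that an arbitrary (e.g. neural) one-step prediction can be treated as a
# linear transition for covariance propagation and likelihood evaluation.
#
# State ordering is fixed throughout the package as [x, vx, y, vy]
# (metres, metres/second).

#' Constant-velocity transition matrix
#'
#' Returns the 4x4 transition matrix of the planar constant-velocity (CV)
#' model for a step of `T` seconds, acting on states ordered
#' `[x, vx, y, vy]`.
#'
#' @param T Step length in seconds (> 0).
#' @return A 4x4 numeric matrix.
#' @export
#' @examples
#' cv_matrix(1) %*% c(0, 10, 0, 0)  # 10 m east after 1 s at 10 m/s
cv_matrix <- function(T) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0) {
    stop("cv_matrix: step length T must be a single positive number",
         call. = FALSE)
  }
  matrix(c(1, T, 0, 0,
           0, 1, 0, 0,
           0, 0, 1, T,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' Constant-turn-rate transition matrix
#'
#' Returns the 4x4 coordinated-turn (CT) transition matrix for turn rate
#' `omega` (rad/s) over a step of `T` seconds. For `|omega|` below 1e-8 the
#' analytic limit, the CV matrix, is returned.
#'
#' @param T Step length in seconds (> 0).
#' @param omega Turn rate in rad/s; positive turns the velocity vector
#'   counter-clockwise.
#' @return A 4x4 numeric matrix.
#' @export
ct_matrix <- function(T, omega) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0) {
    stop("ct_matrix: step length T must be a single positive number",
         call. = FALSE)
  }
  if (abs(omega) < 1e-8) {
    return(cv_matrix(T))
  }
  s <- sin(omega * T)
  c <- cos(omega * T)
  matrix(c(1, s / omega,       0, -(1 - c) / omega,
           0, c,               0, -s,
           0, (1 - c) / omega, 1, s / omega,
           0, s,               0, c), 4, 4, byrow = TRUE)
}

#' Estimate a turn rate from two consecutive state estimates
#'
#' The turn rate is the wrapped change in velocity heading between `prev`
#' and `cur`, divided by the step length. When either velocity is too small
#' to define a heading, 0 is returned (the CV regime).
#'
#' @param prev,cur State vectors `[x, vx, y, vy]` one step apart.
#' @param T Step length in seconds.
#' @return Turn rate in rad/s, in `(-pi/T, pi/T]`.
#' @export
estimate_turn_rate <- function(prev, cur, T) {
  sp_prev <- sqrt(prev[2]^2 + prev[4]^2)
  sp_cur <- sqrt(cur[2]^2 + cur[4]^2)
  if (sp_prev <= 1e-6 || sp_cur <= 1e-6) {
    return(0)
  }
  dtheta <- atan2(cur[4], cur[2]) - atan2(prev[4], prev[2])
  # wrap to (-pi, pi]
  dtheta <- dtheta - 2 * pi * floor((dtheta + pi) / (2 * pi))
  dtheta / T
}

#' Fit the blend coefficient of the approximate transfer matrix
#'
#' Finds `alpha` in `[0, 1]` minimising
#' `|| (alpha F_CV + (1 - alpha) F_CT) x_est - x_pred ||^2`.
#' The problem is a one-dimensional quadratic with closed-form minimiser
#' `alpha* = (u - v) . (t - v) / ||u - v||^2` where `u = F_CV x_est`,
#' `v = F_CT x_est`, `t = x_pred`, clipped to `[0, 1]`. When the two model
#' predictions coincide (`||u - v|| < 1e-12`) the blend is immaterial and 1
#' (pure CV, the simpler model) is returned.
#'
#' @param x_est Current estimated state `[x, vx, y, vy]`.
#' @param x_pred Predicted next state (e.g. from a neural motion model).
#' @param T Step length in seconds.
#' @param omega Turn rate for the CT member, rad/s.
#' @return The fitted blend coefficient in `[0, 1]`.
#' @export
fit_alpha <- function(x_est, x_pred, T, omega) {
  u <- drop(cv_matrix(T) %*% x_est)
  v <- drop(ct_matrix(T, omega) %*% x_est)
  d <- u - v
  nd2 <- sum(d * d)
  if (sqrt(nd2) < 1e-12) {
    return(1)
  }
  a <- sum(d * (x_pred - v)) / nd2
  min(max(a, 0), 1)
}

#' Approximate one-step state-transfer matrix
#'
#' Builds the convex blend `alpha F_CV + (1 - alpha) F_CT` with `alpha`
#' fitted by [fit_alpha()] so that the blend maps `x_est` as close as
#' possible (in least squares) to `x_pred`. The residual of the returned
#' matrix never exceeds the residual of either pure model.
#'
#' @inheritParams fit_alpha
#' @return A list of class `"transfer_matrix"` with elements `F` (4x4
#'   matrix), `alpha`, `T` and `omega`.
#' @export
approx_transfer <- function(x_est, x_pred, T, omega) {
  a <- fit_alpha(x_est, x_pred, T, omega)
  F <- a * cv_matrix(T) + (1 - a) * ct_matrix(T, omega)
  structure(list(F = F, alpha = a, T = T, omega = omega),
            class = "transfer_matrix")
}

#' Propagate a covariance through a linear transition
#'
#' Computes `F S F' + Q` and symmetrises the result to suppress round-off.
#'
#' @param F 4x4 transition matrix (or a `"transfer_matrix"` object).
#' @param S Current state covariance (symmetric PSD).
#' @param Q Process-noise covariance (symmetric PSD).
#' @return The predicted covariance, symmetric.
#' @export
propagate_covariance <- function(F, S, Q) {
  if (inherits(F, "transfer_matrix")) F <- F$F
  if (!all(dim(F) == dim(S)) || !all(dim(S) == dim(Q))) {
    stop("propagate_covariance: F, S and Q must share dimensions",
         call. = FALSE)
  }
  P <- F %*% S %*% t(F) + Q
  (P + t(P)) / 2
}
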