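# Evaluation metrics and the Monte-Carlo experiment harness.

#' Position root-mean-square error of a track
#'
#' Square root of the mean squared Euclidean position error. Velocity
#' components are excluded by default so the metric stays in metres;
#' `full_state = TRUE` includes them.
#'
#' @param track_values A `"track_result"` or an m x 4 state matrix.
#' @param truth m x 4 matrix of true states aligned with the tracked steps
#'   (warm-up rows already excluded).
#' @param mode With a `"track_result"`: compare the `"estimate"` or the
#'   one-step-ahead `"prediction"` to the truth.
#' @param full_state Include velocity components in the error.
#' @return RMSE in metres.
#' @export
rmse <- function(track_values, truth, mode = c("estimate", "prediction"),
                 full_state = FALSE) {
  mode <- match.arg(mode)
  M <- if (inherits(track_values, "track_result")) {
    if (mode == "estimate") track_values$est else track_values$pred
  } else {
    as.matrix(track_values)
  }
  truth <- as.matrix(truth)
  if (nrow(M) != nrow(truth)) {
    stop("rmse: tracked and true sequences differ in length", call. = FALSE)
  }
  cols <- if (full_state) 1:4 else c(1, 3)
  sqrt(mean(rowSums((M[, cols, drop = FALSE] -
                       truth[, cols, drop = FALSE])^2)))
}

#' False detection ratio
#'
#' Fraction of false-alarm occurrences in which the tracker selected the
#' false point: `Nf / Nt`, defined as 0 when no false alarm occurred.
#'
#' @param n_false_selected Number of scans where a false point was chosen.
#' @param n_false_present Number of scans containing a false point.
#' @return Ratio in `[0, 1]`.
#' @export
false_detection_ratio <- function(n_false_selected, n_false_present) {
  stopifnot(n_false_present >= 0)
  if (n_false_selected > n_false_present) {
    stop("false_detection_ratio: more false selections than false-alarm ",
         "occurrences (bookkeeping error)", call. = FALSE)
  }
  if (n_false_present == 0) {
    return(0)
  }
  n_false_selected / n_false_present
}

#' Time-averaged model weights of a track
#'
#' @param track A `"track_result"`.
#' @return Per-model mean probability weight (sums to 1).
#' @export
weight_statistics <- function(track) {
  stopifnot(nrow(track$mu) >= 1)
  colMeans(track$mu)
}

#' Monte-Carlo experiment specification
#'
#' @param scenario `"piecewise"` (random manoeuvring segments) or
#'   `"circular"` (single constant-turn circle).
#' @param delta_t Sampling intervals to sweep (seconds).
#' @param p_fa False-alarm rates to sweep.
#' @param methods Character vector from `{"IMM_GRU", "IMM_GRU_BT", "UKF",
#'   "IMM_UKF", "PF", "GRU_EKF"}`.
#' @param n_monte_carlo Replicates per cell.
#' @param base_seed Master seed; each replicate's scenario seed is derived
#'   from it so methods see matched scans.
#' @param duration Minimum scenario duration in seconds.
#' @param delta_l Sensor resolution (noise scale) in metres.
#' @return A list of class `"experiment_spec"`.
#' @export
experiment_spec <- function(scenario = c("piecewise", "circular"),
                            delta_t = 1:5, p_fa = 0,
                            methods = c("IMM_GRU"),
                            n_monte_carlo = 50L, base_seed = 1L,
                            duration = 250, delta_l = 1) {
  scenario <- match.arg(scenario)
  stopifnot(length(delta_t) >= 1, length(p_fa) >= 1, n_monte_carlo >= 1)
  structure(list(scenario = scenario, delta_t = delta_t, p_fa = p_fa,
                 methods = methods,
                 n_monte_carlo = as.integer(n_monte_carlo),
                 base_seed = as.integer(base_seed),
                 duration = duration, delta_l = delta_l),
            class = "experiment_spec")
}

#' Random piecewise manoeuvring scenario
#'
#' Draws pigeon-like segments ([random_segments()]) until the requested
#' duration is covered and assembles the trajectory.
#'
#' @param seed Integer seed.
#' @param duration Minimum total duration in seconds.
#' @param base_dt Base sampling interval in seconds.
#' @return A `"trajectory"`.
#' @export
piecewise_scenario <- function(seed, duration = 250, base_dt = 0.1) {
  segs <- list()
  total <- 0
  i <- 0L
  while (total < duration) {
    i <- i + 1L
    new <- random_segments(1, seed = seed * 131L + i)
    segs <- c(segs, new)
    total <- total + new[[1]]$duration
  }
  generate_trajectory(segs, base_dt = base_dt)
}

scenario_trajectory <- function(spec, seed) {
  switch(spec$scenario,
         piecewise = piecewise_scenario(seed, spec$duration),
         circular = circular_trajectory(duration = spec$duration))
}

run_method <- function(method, frames, bank, cfg, bcfg, gru_ekf_model,
                       run_seed) {
  switch(method,
    IMM_GRU = track(frames, bank, cfg),
    IMM_GRU_BT = track_backtrack(frames, bank, cfg, backtrack_config()),
    UKF = run_ukf(frames, cfg, bcfg),
    IMM_UKF = run_imm_ukf(frames, cfg, bcfg),
    PF = {
      b <- bcfg
      b$seed <- run_seed
      run_pf(frames, cfg, b)
    },
    GRU_EKF = {
      if (is.null(gru_ekf_model)) {
        stop("run_experiment: method GRU_EKF needs a trained model ",
             "(gru_ekf_model)", call. = FALSE)
      }
      run_gru_ekf(frames, gru_ekf_model, cfg)
    },
    stop("run_experiment: unknown method '", method, "'", call. = FALSE))
}

#' Run a Monte-Carlo tracking experiment
#'
#' For every (method, delta_t, p_fa, replicate) cell: a fresh seeded
#' scenario is generated, downsampled, observed, tracked, and scored. All
#' methods of a given (delta_t, p_fa, replicate) share the same scans
#' (matched seeds). Fully reproducible from (`spec`, `spec$base_seed`).
#'
#' @param spec An [experiment_spec()].
#' @param bank The trained model bank (for the IMM-GRU methods).
#' @param cfg A [tracker_config()].
#' @param bcfg A [baseline_config()] shared by the classical baselines.
#' @param gru_ekf_model Optional single large model for the GRU-EKF method.
#' @return A list of class `"run_report"` with `runs` (one row per run) and
#'   `summary` (means and standard errors per cell).
#' @export
run_experiment <- function(spec, bank, cfg = tracker_config(),
                           bcfg = baseline_config("UKF"),
                           gru_ekf_model = NULL) {
  rows <- list()
  for (di in seq_along(spec$delta_t)) {
    dt <- spec$delta_t[di]
    for (pi in seq_along(spec$p_fa)) {
      pfa <- spec$p_fa[pi]
      for (rep_i in seq_len(spec$n_monte_carlo)) {
        # independent of the delta_t index: the same replicate sees the
        # same underlying trajectory across the sampling-interval sweep
        run_seed <- spec$base_seed + 7919L * rep_i + 13L * pi
        traj <- scenario_trajectory(spec, run_seed)
        down <- downsample_trajectory(traj, dt)
        frames <- observe_trajectory(
          down, sim_config(delta_t = dt, delta_l = spec$delta_l,
                           p_fa = pfa, seed = run_seed + 1L))
        warm <- cfg$window_len + 1L
        truth <- down$states[-(seq_len(warm)), , drop = FALSE]
        for (method in spec$methods) {
          res <- run_method(method, frames, bank, cfg, bcfg,
                            gru_ekf_model, run_seed)
          ws <- weight_statistics(res)
          rows[[length(rows) + 1L]] <- data.frame(
            method = method, delta_t = dt, p_fa = pfa, rep = rep_i,
            seed = run_seed,
            est_rmse = rmse(res, truth, "estimate"),
            pred_rmse = rmse(res, truth, "prediction"),
            n_false_present = res$n_false_present,
            n_false_selected = res$n_false_selected,
            fdr = false_detection_ratio(res$n_false_selected,
                                        res$n_false_present),
            mu_mean = I(list(ws)),
            n_steps = length(res$time))
        }
      }
    }
  }
  runs <- do.call(rbind, rows)
  key <- interaction(runs$method, runs$delta_t, runs$p_fa, drop = TRUE)
  summ <- do.call(rbind, lapply(split(runs, key), function(g) {
    data.frame(method = g$method[1], delta_t = g$delta_t[1],
               p_fa = g$p_fa[1], n_runs = nrow(g),
               est_rmse = mean(g$est_rmse),
               est_rmse_se = stats::sd(g$est_rmse) / sqrt(nrow(g)),
               pred_rmse = mean(g$pred_rmse),
               pred_rmse_se = stats::sd(g$pred_rmse) / sqrt(nrow(g)),
               fdr = sum(g$n_false_selected) /
                 max(1, sum(g$n_false_present)))
  }))
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ, spec = spec),
            class = "run_report")
}
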