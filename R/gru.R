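# GRU-based motion models.
#
# Each motion model is a small stacked bidirectional GRU that maps a window
# of L (estimate, measurement) pairs to the next normalized state. The
# forward/backward passes and the Adam optimiser are implemented here with
# plain matrix algebra: the network is tiny (2 layers, 32 hidden units) and
# the learned one-step predictor is the core of the method, so it is
# authored in full rather than delegated.
#
# Gate layout follows the standard GRU:
#   r = sigmoid(x Wi_r + bi_r + h Wh_r + bh_r)
#   z = sigmoid(x Wi_z + bi_z + h Wh_z + bh_z)
#   n = tanh(x Wi_n + bi_n + r * (h Wh_n + bh_n))
#   h' = (1 - z) * n + z * h
# with the three gates stored as column blocks [r | z | n] of Wi, Wh.

#' GRU motion-model architecture configuration
#'
#' @param num_layers Number of stacked bidirectional GRU layers (M >= 1).
#' @param hidden_dim Hidden feature dimension per direction.
#' @param window_len Input window length L (>= 2).
#' @param dropout Dropout probability applied between stacked layers during
#'   training (0 <= p < 1); inference always runs with dropout off.
#' @param input_dim Per-step input dimension (4 state + 4 measurement).
#' @param output_dim Output dimension (the 4 state components).
#' @return A list of class `"gru_config"`.
#' @export
gru_config <- function(num_layers = 2L, hidden_dim = 32L, window_len = 7L,
                       dropout = 0.1, input_dim = 8L, output_dim = 4L) {
  stopifnot(num_layers >= 1, window_len >= 2, dropout >= 0, dropout < 1,
            hidden_dim >= 1)
  structure(list(num_layers = as.integer(num_layers),
                 hidden_dim = as.integer(hidden_dim),
                 window_len = as.integer(window_len),
                 dropout = dropout,
                 input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim)),
            class = "gru_config")
}

#' Training configuration
#'
#' Defaults follow the training protocol the motion models were designed
#' for: Adam with decoupled weight decay, an initial learning rate of 0.01
#' under a cosine-annealing schedule restarting every five epochs, batch
#' size 256, mean-squared-error loss, and early stopping once the
#' validation loss has not improved for `patience` epochs.
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate Initial Adam learning rate.
#' @param weight_decay Decoupled weight-decay coefficient. The default 0.5
#'   is the protocol value; it is unusually large for this optimiser family
#'   and 1e-2 is a reasonable fallback if training stalls.
#' @param epochs_per_cycle Cosine-annealing cycle length in epochs.
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Hard cap on training epochs.
#' @param seed Integer seed controlling initialisation, shuffling, dropout
#'   and the train/validation/test split.
#' @return A list of class `"train_config"`. The loss is always MSE.
#' @export
train_config <- function(batch_size = 256L, learning_rate = 0.01,
                         weight_decay = 0.5, epochs_per_cycle = 5L,
                         patience = 20L, max_epochs = 200L, seed = 1L) {
  stopifnot(batch_size >= 1, learning_rate > 0, weight_decay >= 0,
            epochs_per_cycle >= 1, patience >= 1, max_epochs >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 epochs_per_cycle = as.integer(epochs_per_cycle),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

param_name <- function(layer, dir, what) {
  sprintf("L%d.%s.%s", layer, dir, what)
}

#' Initialise an untrained GRU motion model
#'
#' Weights are drawn uniformly from `(-1/sqrt(H), 1/sqrt(H))`.
#'
#' @param cfg A [gru_config()].
#' @param norm Normalisation constants: list with `pos_scale` (m) and
#'   `vel_scale` (m/s); see [normalize_window()].
#' @param delta_t_bin Length-2 numeric, the sampling-interval band
#'   (seconds) this model is trained for.
#' @param seed Integer seed for the weight draw.
#' @return A list of class `"gru_motion_model"`.
#' @export
new_gru_model <- function(cfg, norm, delta_t_bin, seed = 1L) {
  stopifnot(inherits(cfg, "gru_config"), norm$pos_scale > 0,
            norm$vel_scale > 0)
  H <- cfg$hidden_dim
  k <- 1 / sqrt(H)
  params <- list()
  with_seed(seed, {
    for (m in seq_len(cfg$num_layers)) {
      d_in <- if (m == 1L) cfg$input_dim else H
      for (dir in c("fwd", "bwd")) {
        params[[param_name(m, dir, "Wi")]] <-
          matrix(stats::runif(d_in * 3 * H, -k, k), d_in, 3 * H)
        params[[param_name(m, dir, "Wh")]] <-
          matrix(stats::runif(H * 3 * H, -k, k), H, 3 * H)
        params[[param_name(m, dir, "bi")]] <- stats::runif(3 * H, -k, k)
        params[[param_name(m, dir, "bh")]] <- stats::runif(3 * H, -k, k)
      }
    }
    params[["head.W"]] <-
      matrix(stats::runif(H * cfg$output_dim, -k, k), H, cfg$output_dim)
    params[["head.b"]] <- stats::runif(cfg$output_dim, -k, k)
  })
  structure(list(config = cfg, params = params, norm = norm,
                 delta_t_bin = delta_t_bin, seed = as.integer(seed),
                 history = NULL),
            class = "gru_motion_model")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(A, b) A + rep(b, each = nrow(A))

# One direction of one GRU layer over a window.
# X: list of L matrices (B x d_in); order: time indices in processing order.
# Returns per-step hidden outputs and, optionally, the caches BPTT needs.
gru_dir_forward <- function(X, Wi, Wh, bi, bh, order, keep_cache = FALSE) {
  B <- nrow(X[[1]])
  H <- nrow(Wh)
  ir <- seq_len(H); iz <- H + ir; inn <- 2 * H + ir
  h <- matrix(0, B, H)
  out <- vector("list", length(X))
  cache <- if (keep_cache) vector("list", length(X)) else NULL
  for (t in order) {
    gi <- add_bias(X[[t]] %*% Wi, bi)
    gh <- add_bias(h %*% Wh, bh)
    r <- sigmoid(gi[, ir, drop = FALSE] + gh[, ir, drop = FALSE])
    z <- sigmoid(gi[, iz, drop = FALSE] + gh[, iz, drop = FALSE])
    ghn <- gh[, inn, drop = FALSE]
    n <- tanh(gi[, inn, drop = FALSE] + r * ghn)
    hprev <- h
    h <- (1 - z) * n + z * hprev
    out[[t]] <- h
    if (keep_cache) {
      cache[[t]] <- list(r = r, z = z, n = n, hprev = hprev, ghn = ghn)
    }
  }
  list(out = out, cache = cache)
}

# Backprop through one direction. dOut: list of B x H grads w.r.t. this
# direction's per-step output. Returns parameter grads and dX per step.
gru_dir_backward <- function(X, Wi, Wh, dOut, fwd, order) {
  B <- nrow(X[[1]])
  H <- nrow(Wh)
  dWi <- Wi * 0; dWh <- Wh * 0
  dbi <- numeric(3 * H); dbh <- numeric(3 * H)
  dX <- vector("list", length(X))
  dh_carry <- matrix(0, B, H)
  for (t in rev(order)) {
    cc <- fwd$cache[[t]]
    dh <- dOut[[t]] + dh_carry
    dz <- dh * (cc$hprev - cc$n)
    dn <- dh * (1 - cc$z)
    dh_carry <- dh * cc$z
    dan <- dn * (1 - cc$n^2)
    dr <- dan * cc$ghn
    dghn <- dan * cc$r
    dar <- dr * cc$r * (1 - cc$r)
    daz <- dz * cc$z * (1 - cc$z)
    dgi <- cbind(dar, daz, dan)
    dgh <- cbind(dar, daz, dghn)
    dWi <- dWi + crossprod(X[[t]], dgi)
    dWh <- dWh + crossprod(cc$hprev, dgh)
    dbi <- dbi + colSums(dgi)
    dbh <- dbh + colSums(dgh)
    dX[[t]] <- dgi %*% t(Wi)
    dh_carry <- dh_carry + dgh %*% t(Wh)
  }
  list(dWi = dWi, dWh = dWh, dbi = dbi, dbh = dbh, dX = dX)
}

# Full-network batched forward. Xarr: B x L x input_dim array. Returns the
# B x 4 normalized prediction and (when keep_cache) everything backward
# needs. Dropout masks are drawn from the session RNG when train = TRUE.
gru_forward_batch <- function(model, Xarr, train = FALSE,
                              keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  L <- cfg$window_len
  B <- dim(Xarr)[1]
  X <- lapply(seq_len(L), function(t) {
    matrix(Xarr[, t, ], nrow = B)
  })
  order_f <- seq_len(L)
  order_b <- rev(order_f)
  layers <- vector("list", cfg$num_layers)
  masks <- vector("list", cfg$num_layers)
  inp <- X
  for (m in seq_len(cfg$num_layers)) {
    fwd <- gru_dir_forward(inp, p[[param_name(m, "fwd", "Wi")]],
                           p[[param_name(m, "fwd", "Wh")]],
                           p[[param_name(m, "fwd", "bi")]],
                           p[[param_name(m, "fwd", "bh")]],
                           order_f, keep_cache)
    bwd <- gru_dir_forward(inp, p[[param_name(m, "bwd", "Wi")]],
                           p[[param_name(m, "bwd", "Wh")]],
                           p[[param_name(m, "bwd", "bi")]],
                           p[[param_name(m, "bwd", "bh")]],
                           order_b, keep_cache)
    out <- lapply(seq_len(L), function(t) fwd$out[[t]] + bwd$out[[t]])
    if (train && cfg$dropout > 0 && m < cfg$num_layers) {
      mk <- lapply(seq_len(L), function(t) {
        matrix(stats::rbinom(B * cfg$hidden_dim, 1, 1 - cfg$dropout),
               B, cfg$hidden_dim) / (1 - cfg$dropout)
      })
      out <- lapply(seq_len(L), function(t) out[[t]] * mk[[t]])
      masks[[m]] <- mk
    }
    layers[[m]] <- list(input = inp, fwd = fwd, bwd = bwd, out = out)
    inp <- out
  }
  hL <- inp[[L]]
  a <- add_bias(hL %*% p[["head.W"]], p[["head.b"]])
  y <- tanh(a)
  res <- list(y = y)
  if (keep_cache) {
    res$layers <- layers
    res$masks <- masks
    res$hL <- hL
  }
  res
}

# Full-network backward for MSE-style upstream grad dY (B x 4).
# Returns a flat named list of parameter gradients.
gru_backward_batch <- function(model, fw, dY) {
  cfg <- model$config
  p <- model$params
  L <- cfg$window_len
  B <- nrow(dY)
  H <- cfg$hidden_dim
  grads <- list()
  da <- dY * (1 - fw$y^2)
  grads[["head.W"]] <- crossprod(fw$hL, da)
  grads[["head.b"]] <- colSums(da)
  dOut_top <- lapply(seq_len(L), function(t) matrix(0, B, H))
  dOut_top[[L]] <- da %*% t(p[["head.W"]])
  dOut <- dOut_top
  order_f <- seq_len(L)
  order_b <- rev(order_f)
  for (m in rev(seq_len(cfg$num_layers))) {
    ly <- fw$layers[[m]]
    if (!is.null(fw$masks[[m]])) {
      dOut <- lapply(seq_len(L), function(t) dOut[[t]] * fw$masks[[m]][[t]])
    }
    gf <- gru_dir_backward(ly$input, p[[param_name(m, "fwd", "Wi")]],
                           p[[param_name(m, "fwd", "Wh")]],
                           dOut, ly$fwd, order_f)
    gb <- gru_dir_backward(ly$input, p[[param_name(m, "bwd", "Wi")]],
                           p[[param_name(m, "bwd", "Wh")]],
                           dOut, ly$bwd, order_b)
    grads[[param_name(m, "fwd", "Wi")]] <- gf$dWi
    grads[[param_name(m, "fwd", "Wh")]] <- gf$dWh
    grads[[param_name(m, "fwd", "bi")]] <- gf$dbi
    grads[[param_name(m, "fwd", "bh")]] <- gf$dbh
    grads[[param_name(m, "bwd", "Wi")]] <- gb$dWi
    grads[[param_name(m, "bwd", "Wh")]] <- gb$dWh
    grads[[param_name(m, "bwd", "bi")]] <- gb$dbi
    grads[[param_name(m, "bwd", "bh")]] <- gb$dbh
    dOut <- lapply(seq_len(L), function(t) gf$dX[[t]] + gb$dX[[t]])
  }
  grads
}

#' Normalise an input window
#'
#' Positions (of both the estimate and the measurement channel) are
#' expressed as displacements from the reference state's position divided
#' by `norm$pos_scale`; velocities are divided by `norm$vel_scale`. The
#' transform is invertible given (`ref`, `norm`), translation-invariant,
#' and keeps well-behaved targets inside the tanh head's (-1, 1) range.
#'
#' @param est_hist L x 4 matrix of state estimates, oldest row first.
#' @param meas_hist L x 4 matrix of measurements, same ordering.
#' @param ref Reference state `[x, vx, y, vy]`; by convention the newest
#'   estimate in the window.
#' @param norm List with `pos_scale` (m) and `vel_scale` (m/s).
#' @return An L x 8 matrix, columns 1-4 the normalised estimates and 5-8
#'   the normalised measurements.
#' @export
normalize_window <- function(est_hist, meas_hist, ref, norm) {
  est_hist <- as.matrix(est_hist); meas_hist <- as.matrix(meas_hist)
  if (nrow(est_hist) != nrow(meas_hist)) {
    stop("normalize_window: estimate and measurement histories differ ",
         "in length", call. = FALSE)
  }
  nrm <- function(M) {
    cbind((M[, 1] - ref[1]) / norm$pos_scale,
          M[, 2] / norm$vel_scale,
          (M[, 3] - ref[3]) / norm$pos_scale,
          M[, 4] / norm$vel_scale)
  }
  cbind(nrm(est_hist), nrm(meas_hist))
}

#' Map a normalised state back to absolute coordinates
#'
#' Inverse of the per-state transform used by [normalize_window()].
#'
#' @param y Normalised 4-vector (or n x 4 matrix).
#' @param ref Reference state used at normalisation time.
#' @param norm Normalisation constants.
#' @return Absolute state(s) `[x, vx, y, vy]`.
#' @export
denormalize_state <- function(y, ref, norm) {
  if (is.matrix(y)) {
    cbind(y[, 1] * norm$pos_scale + ref[1],
          y[, 2] * norm$vel_scale,
          y[, 3] * norm$pos_scale + ref[3],
          y[, 4] * norm$vel_scale)
  } else {
    c(y[1] * norm$pos_scale + ref[1],
      y[2] * norm$vel_scale,
      y[3] * norm$pos_scale + ref[3],
      y[4] * norm$vel_scale)
  }
}

normalize_state <- function(x, ref, norm) {
  c((x[1] - ref[1]) / norm$pos_scale,
    x[2] / norm$vel_scale,
    (x[3] - ref[3]) / norm$pos_scale,
    x[4] / norm$vel_scale)
}

#' Predict the next state with a trained GRU motion model
#'
#' Runs the network in inference mode (dropout off, deterministic) on one
#' window of estimate/measurement history and returns the absolute
#' predicted next state.
#'
#' @param model A `"gru_motion_model"`.
#' @param est_hist,meas_hist L x 4 history matrices, oldest row first.
#' @return Predicted state `[x, vx, y, vy]` one step ahead.
#' @export
gru_predict <- function(model, est_hist, meas_hist) {
  cfg <- model$config
  if (nrow(est_hist) != cfg$window_len) {
    stop("gru_predict: window length mismatch", call. = FALSE)
  }
  ref <- est_hist[cfg$window_len, ]
  W <- normalize_window(est_hist, meas_hist, ref, model$norm)
  Xarr <- array(W, dim = c(1, cfg$window_len, cfg$input_dim))
  fw <- gru_forward_batch(model, Xarr, train = FALSE)
  denormalize_state(drop(fw$y), ref, model$norm)
}

#' Build a supervised training set for one sampling-interval band
#'
#' For every trajectory and every sampling interval `delta_t` in the band
#' (0.1 s grid), the trajectory is downsampled, observed with position
#' noise (no false alarms during training), and a length-L window slides
#' over the resampled track. The estimate channel is teacher-forced with
#' the ground-truth states; the measurement channel holds the noisy
#' observations; the target is the next true state. Windows start at the
#' second resampled point (the first has no backward-difference velocity).
#' All windows are normalised with the band's scale constants and shuffled.
#'
#' @param trajectories List of `"trajectory"` objects at the base sampling
#'   interval.
#' @param bin Length-2 numeric `[lo, hi]`, the delta-t band in seconds.
#' @param sim_cfg A [sim_config()]; its `delta_l` and `seed` are used
#'   (`p_fa` is forced to 0 for training data).
#' @param gru_cfg A [gru_config()] (for the window length).
#' @param v_max Speed scale in m/s used to build the normalisation
#'   constants `pos_scale = v_max * L * hi`, `vel_scale = v_max`.
#' @param max_windows Optional cap on the number of windows (seeded
#'   subsample).
#' @return A list with `windows` (N x L x 8 array), `targets` (N x 4,
#'   normalised), `norm`, `bin` and `n_skipped` (trajectories too short for
#'   a window at some delta-t).
#' @export
make_training_set <- function(trajectories, bin, sim_cfg, gru_cfg,
                              v_max = 30, max_windows = NULL) {
  stopifnot(bin[1] >= 0.1 - 1e-9, bin[2] <= 5 + 1e-9, bin[1] <= bin[2])
  L <- gru_cfg$window_len
  norm <- list(pos_scale = v_max * L * bin[2], vel_scale = v_max)
  dts <- seq(bin[1], bin[2] + 1e-9, by = 0.1)
  windows <- list()
  targets <- list()
  n_skipped <- 0L
  obs_seed <- sim_cfg$seed
  for (dt in dts) {
    for (ti in seq_along(trajectories)) {
      traj <- trajectories[[ti]]
      down <- downsample_trajectory(traj, dt)
      n <- length(down$times)
      if (n < L + 2) {
        n_skipped <- n_skipped + 1L
        warning(sprintf(
          "make_training_set: trajectory %d too short at delta_t = %.1f s",
          ti, dt), call. = FALSE)
        next
      }
      obs_seed <- obs_seed + 1L
      frames <- observe_trajectory(
        down, sim_config(delta_t = dt, delta_l = sim_cfg$delta_l,
                         p_fa = 0, seed = obs_seed))
      meas <- t(vapply(frames, function(fr) fr$points[fr$truth_index, ],
                       numeric(4)))
      for (i in 2:(n - L)) {
        rows <- i:(i + L - 1)
        est <- down$states[rows, , drop = FALSE]
        ref <- est[L, ]
        windows[[length(windows) + 1L]] <-
          normalize_window(est, meas[rows, , drop = FALSE], ref, norm)
        targets[[length(targets) + 1L]] <-
          normalize_state(down$states[i + L, ], ref, norm)
      }
    }
  }
  N <- length(windows)
  if (N == 0L) {
    stop("make_training_set: no usable windows", call. = FALSE)
  }
  ord <- with_seed(sim_cfg$seed, sample.int(N))
  if (!is.null(max_windows) && N > max_windows) {
    ord <- ord[seq_len(max_windows)]
    N <- max_windows
  }
  Warr <- array(0, dim = c(N, L, gru_cfg$input_dim))
  Tg <- matrix(0, N, 4)
  for (j in seq_len(N)) {
    Warr[j, , ] <- windows[[ord[j]]]
    Tg[j, ] <- targets[[ord[j]]]
  }
  list(windows = Warr, targets = Tg, norm = norm, bin = bin,
       n_skipped = n_skipped)
}

subset_batch <- function(Xarr, idx) {
  Xarr[idx, , , drop = FALSE]
}

batch_loss_grad <- function(model, Xb, Tb, train = TRUE) {
  fw <- gru_forward_batch(model, Xb, train = train, keep_cache = TRUE)
  err <- fw$y - Tb
  loss <- mean(err^2)
  dY <- 2 * err / length(err)
  grads <- gru_backward_batch(model, fw, dY)
  list(loss = loss, grads = grads)
}

eval_loss <- function(model, Xarr, Tg, batch = 1024L) {
  n <- dim(Xarr)[1]
  if (n == 0L) return(NA_real_)
  tot <- 0
  for (s in seq(1, n, by = batch)) {
    idx <- s:min(s + batch - 1, n)
    fw <- gru_forward_batch(model, subset_batch(Xarr, idx), train = FALSE)
    tot <- tot + sum((fw$y - Tg[idx, , drop = FALSE])^2)
  }
  tot / (n * ncol(Tg))
}

#' Train a GRU motion model on one band's dataset
#'
#' Minimises the MSE between the predicted and true normalised next states
#' with Adam plus decoupled weight decay under a cosine-annealing learning
#' rate restarting every `epochs_per_cycle` epochs. The dataset is split
#' 8:1:1 into train/validation/test by a seeded permutation; training stops
#' when the validation loss has not improved for `patience` epochs (or at
#' `max_epochs`) and the best-validation checkpoint is returned.
#'
#' @param dataset Output of [make_training_set()].
#' @param gru_cfg A [gru_config()].
#' @param cfg A [train_config()].
#' @return A trained `"gru_motion_model"`; `$history` records per-epoch
#'   train/validation losses and the held-out test loss.
#' @export
train_model <- function(dataset, gru_cfg, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  N <- dim(dataset$windows)[1]
  split <- with_seed(cfg$seed + 7L, sample.int(N))
  n_tr <- max(1L, floor(0.8 * N))
  n_va <- max(1L, floor(0.1 * N))
  i_tr <- split[seq_len(n_tr)]
  i_va <- split[(n_tr + 1):min(n_tr + n_va, N)]
  i_te <- if (n_tr + n_va < N) split[(n_tr + n_va + 1):N] else i_va
  Xtr <- subset_batch(dataset$windows, i_tr)
  Ttr <- dataset$targets[i_tr, , drop = FALSE]
  Xva <- subset_batch(dataset$windows, i_va)
  Tva <- dataset$targets[i_va, , drop = FALSE]

  model <- new_gru_model(gru_cfg, dataset$norm, dataset$bin,
                         seed = cfg$seed)
  opt <- adam_init(model$params)
  best <- model$params
  best_val <- eval_loss(model, Xva, Tva)
  wait <- 0L
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train = numeric(), val = numeric())
  n_batches <- ceiling(nrow(Ttr) / cfg$batch_size)

  with_seed(cfg$seed + 13L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      phase <- ((epoch - 1) %% cfg$epochs_per_cycle) / cfg$epochs_per_cycle
      lr <- cfg$learning_rate * 0.5 * (1 + cos(pi * phase))
      perm <- sample.int(nrow(Ttr))
      ep_loss <- 0
      for (b in seq_len(n_batches)) {
        idx <- perm[((b - 1) * cfg$batch_size + 1):
                      min(b * cfg$batch_size, nrow(Ttr))]
        bl <- batch_loss_grad(model, subset_batch(Xtr, idx),
                              Ttr[idx, , drop = FALSE], train = TRUE)
        if (!is.finite(bl$loss)) {
          stop(sprintf(
            "train_model: non-finite loss at epoch %d batch %d (lr %.4g)",
            epoch, b, lr), call. = FALSE)
        }
        ep_loss <- ep_loss + bl$loss * length(idx)
        step <- adam_step(opt, model$params, bl$grads, lr,
                          cfg$weight_decay)
        model$params <- step$params
        opt <- step$opt
      }
      val <- eval_loss(model, Xva, Tva)
      hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                     train = ep_loss / nrow(Ttr),
                                     val = val))
      if (is.finite(val) && val < best_val - 1e-12) {
        best_val <- val
        best <- model$params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  model$params <- best
  Xte <- subset_batch(dataset$windows, i_te)
  Tte <- dataset$targets[i_te, , drop = FALSE]
  model$history <- list(epochs = hist, best_val = best_val,
                        test = eval_loss(model, Xte, Tte))
  model
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(opt, params, grads, lr, weight_decay) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + opt$eps) -
      lr * weight_decay * params[[nm]]
  }
  list(opt = opt, params = params)
}

#' Partition the sampling-interval range into model bands
#'
#' The 0.1-5.0 s grid (0.1 s steps, 50 values) is split into `n` contiguous
#' groups as equal as possible; `n = 5` gives the canonical bands
#' `[0.1,1], [1.1,2], [2.1,3], [3.1,4], [4.1,5]`.
#'
#' @param n_models Number of bands (>= 1).
#' @return A list of length-2 numeric vectors `[lo, hi]`.
#' @export
delta_t_bins <- function(n_models) {
  stopifnot(n_models >= 1)
  grid <- round(seq(0.1, 5, by = 0.1), 10)
  sizes <- rep(length(grid) %/% n_models, n_models)
  extra <- length(grid) %% n_models
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n_models), function(j) c(grid[starts[j]], grid[ends[j]]))
}

#' Train a bank of GRU motion models
#'
#' Splits the 0.1-5 s sampling-interval range into `n_models` contiguous
#' bands ([delta_t_bins()]), builds one training set per band and trains
#' one model per band. Models are returned ordered from the slowest
#' motion-change band (model 1) to the fastest.
#'
#' @param trajectories Training trajectories at the base sampling interval.
#' @param n_models Number of bank members.
#' @param gru_cfg A [gru_config()].
#' @param train_cfg A [train_config()].
#' @param sim_cfg A [sim_config()] controlling the training noise level.
#' @param v_max Normalisation speed scale, m/s.
#' @param max_windows_per_bin Cap on windows per band.
#' @return A list of class `"model_bank"` of trained models.
#' @export
build_bank <- function(trajectories, n_models, gru_cfg, train_cfg, sim_cfg,
                       v_max = 30, max_windows_per_bin = 2000L) {
  bins <- delta_t_bins(n_models)
  models <- vector("list", n_models)
  for (j in seq_len(n_models)) {
    ds <- make_training_set(
      trajectories, bins[[j]],
      sim_config(delta_t = bins[[j]][2], delta_l = sim_cfg$delta_l,
                 p_fa = 0, seed = sim_cfg$seed + 1000L * j),
      gru_cfg, v_max = v_max, max_windows = max_windows_per_bin)
    tc <- train_cfg
    tc$seed <- train_cfg$seed + j
    models[[j]] <- train_model(ds, gru_cfg, tc)
  }
  structure(models, class = "model_bank")
}

#' Save / load a model bank as JSON checkpoints
#'
#' One JSON file per model (`model_1.json`, ...) holding the architecture,
#' normalisation constants, band, seed and all weights.
#'
#' @param bank A `"model_bank"`.
#' @param dir Directory (created if missing).
#' @export
save_bank <- function(bank, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (j in seq_along(bank)) {
    m <- bank[[j]]
    obj <- list(config = unclass(m$config), norm = m$norm,
                delta_t_bin = m$delta_t_bin, seed = m$seed,
                params = lapply(m$params, function(p) {
                  if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                  else list(dim = NULL, data = as.numeric(p))
                }))
    jsonlite::write_json(obj, file.path(dir, sprintf("model_%d.json", j)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname save_bank
#' @export
load_bank <- function(dir) {
  files <- sort(list.files(dir, pattern = "^model_\\d+\\.json$",
                           full.names = TRUE))
  if (length(files) == 0) {
    stop("load_bank: no model checkpoints in ", dir, call. = FALSE)
  }
  ord <- order(as.integer(sub("^model_(\\d+)\\.json$", "\\1",
                              basename(files))))
  models <- lapply(files[ord], function(f) {
    obj <- jsonlite::read_json(f, simplifyVector = TRUE)
    cfg <- do.call(gru_config, as.list(obj$config))
    params <- lapply(obj$params, function(p) {
      if (!is.null(p$dim) && length(p$dim) == 2) {
        matrix(p$data, p$dim[1], p$dim[2])
      } else {
        as.numeric(p$data)
      }
    })
    structure(list(config = cfg, params = params,
                   norm = as.list(obj$norm),
                   delta_t_bin = as.numeric(obj$delta_t_bin),
                   seed = obj$seed, history = NULL),
              class = "gru_motion_model")
  })
  structure(models, class = "model_bank")
}

#' One-step prediction interface for bank members
#'
#' Every bank member implements `predict_next(model, est_hist, meas_hist,
#' T)`: given the model's own L-step estimate history and the shared
#' measurement history, return the predicted next state. Besides the GRU
#' models, an analytic constant-velocity predictor ([cv_predictor()]) is
#' provided; a bank of one CV predictor reduces the whole tracking loop to
#' a textbook constant-velocity Kalman filter.
#'
#' @param model A bank member.
#' @param est_hist,meas_hist L x 4 history matrices, oldest row first.
#' @param T Step length in seconds.
#' @return Predicted state `[x, vx, y, vy]`.
#' @export
predict_next <- function(model, est_hist, meas_hist, T) {
  UseMethod("predict_next")
}

#' @export
predict_next.gru_motion_model <- function(model, est_hist, meas_hist, T) {
  gru_predict(model, est_hist, meas_hist)
}

#' Analytic constant-velocity predictor
#'
#' A drop-in bank member whose prediction is exactly `F_CV(T) x_est`; used
#' to validate that the tracking loop reduces to a standard Kalman filter.
#'
#' @return An object of class `"cv_predictor"`.
#' @export
cv_predictor <- function() {
  structure(list(), class = "cv_predictor")
}

#' @export
predict_next.cv_predictor <- function(model, est_hist, meas_hist, T) {
  drop(cv_matrix(T) %*% est_hist[nrow(est_hist), ])
}
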