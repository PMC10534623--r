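# Trajectory and scan simulator.
#
# Generates piecewise-manoeuvring planar trajectories (constant velocity,
# constant turn rate, constant tangential acceleration) at a fine base
# sampling interval, then emulates a low-refresh-rate scanning sensor:
# downsampling, additive Gaussian position noise of variance 4*delta_l^2
# (delta_l is the sensor's range resolution in metres), velocity observed by
# differencing adjacent noisy positions, and occasional false-alarm points.

#' Specify one trajectory segment
#'
#' @param kind One of `"CV"` (straight, constant speed), `"CT"` (constant
#'   turn rate) or `"CA"` (straight, constant tangential acceleration).
#' @param duration Segment length in seconds (> 0).
#' @param speed Speed at segment start, m/s (>= 0).
#' @param turn_rate Turn rate in rad/s (CT only; positive = counter-clockwise).
#' @param accel Tangential acceleration in m/s^2 (CA only).
#' @return A list of class `"segment_spec"`.
#' @export
segment_spec <- function(kind, duration, speed,
                         turn_rate = 0, accel = 0) {
  if (!kind %in% c("CV", "CT", "CA")) {
    stop("segment_spec: unknown segment kind '", kind,
         "' (expected CV, CT or CA)", call. = FALSE)
  }
  stopifnot(duration > 0, speed >= 0)
  structure(list(kind = kind, duration = duration, speed = speed,
                 turn_rate = turn_rate, accel = accel),
            class = "segment_spec")
}

# Analytic state of one segment at local time tau, given entry position and
# heading. Returns c(x, vx, y, vy) and, via attribute, exit heading.
segment_state <- function(seg, tau, x0, y0, theta0) {
  sp <- seg$speed
  switch(seg$kind,
    CV = {
      c(x0 + sp * tau * cos(theta0), sp * cos(theta0),
        y0 + sp * tau * sin(theta0), sp * sin(theta0))
    },
    CT = {
      w <- seg$turn_rate
      if (abs(w) < 1e-12) {
        return(segment_state(segment_spec("CV", seg$duration, sp), tau,
                             x0, y0, theta0))
      }
      th <- theta0 + w * tau
      c(x0 + sp / w * (sin(th) - sin(theta0)), sp * cos(th),
        y0 - sp / w * (cos(th) - cos(theta0)), sp * sin(th))
    },
    CA = {
      a <- seg$accel
      s <- sp * tau + a * tau^2 / 2
      v <- sp + a * tau
      c(x0 + s * cos(theta0), v * cos(theta0),
        y0 + s * sin(theta0), v * sin(theta0))
    })
}

#' Generate a piecewise-manoeuvring ground-truth trajectory
#'
#' Concatenates the analytic kinematics of each segment; position and
#' heading are continuous across joins (speed follows each segment's own
#' specification). Sampling is uniform at `base_dt` starting at time 0. The
#' kinematics are deterministic; `seed` is accepted for interface symmetry
#' with the stochastic generators and ignored.
#'
#' @param segments Non-empty list of [segment_spec()] objects.
#' @param base_dt Base sampling interval in seconds (> 0).
#' @param x0,y0,theta0 Initial position (m) and heading (rad).
#' @param seed Ignored (the generator is deterministic).
#' @return A list of class `"trajectory"` with `times` (seconds), `states`
#'   (N x 4 matrix, columns `x, vx, y, vy`) and `base_dt`.
#' @export
generate_trajectory <- function(segments, base_dt, x0 = 0, y0 = 0,
                                theta0 = 0, seed = NULL) {
  if (length(segments) == 0) {
    stop("generate_trajectory: at least one segment required", call. = FALSE)
  }
  stopifnot(base_dt > 0)
  for (seg in segments) {
    if (!inherits(seg, "segment_spec")) {
      stop("generate_trajectory: segments must be built with segment_spec()",
           call. = FALSE)
    }
  }
  durations <- vapply(segments, `[[`, numeric(1), "duration")
  starts <- cumsum(c(0, durations))
  total <- starts[length(starts)]
  times <- seq(0, total + 1e-9, by = base_dt)
  times <- times[times <= total + 1e-9]

  # entry state (position, heading) of each segment
  entry <- vector("list", length(segments))
  px <- x0; py <- y0; th <- theta0
  for (i in seq_along(segments)) {
    entry[[i]] <- list(x = px, y = py, theta = th)
    seg <- segments[[i]]
    st <- segment_state(seg, seg$duration, px, py, th)
    px <- st[1]; py <- st[3]
    th <- switch(seg$kind,
                 CT = th + seg$turn_rate * seg$duration,
                 th)
  }

  states <- matrix(0, length(times), 4,
                   dimnames = list(NULL, c("x", "vx", "y", "vy")))
  for (k in seq_along(times)) {
    t <- times[k]
    i <- findInterval(t, starts, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(segments))
    e <- entry[[i]]
    states[k, ] <- segment_state(segments[[i]], t - starts[i],
                                 e$x, e$y, e$theta)
  }
  structure(list(times = times, states = states, base_dt = base_dt),
            class = "trajectory")
}

#' Draw a random pigeon-like segment sequence
#'
#' Segments alternate between straight flight and turns with speeds of
#' 10-20 m/s, turn rates up to 0.5 rad/s in magnitude and durations of
#' 5-60 s, the regime of free-flying pigeons.
#'
#' @param n_segments Number of segments.
#' @param seed Integer seed (reproducible).
#' @return A list of [segment_spec()] objects.
#' @export
random_segments <- function(n_segments, seed) {
  stopifnot(n_segments >= 1)
  with_seed(seed, {
    segs <- vector("list", n_segments)
    for (i in seq_len(n_segments)) {
      kind <- sample(c("CV", "CT", "CT", "CA"), 1)  # turns dominate
      dur <- stats::runif(1, 5, 60)
      sp <- stats::runif(1, 10, 20)
      segs[[i]] <- switch(kind,
        CV = segment_spec("CV", dur, sp),
        CT = segment_spec("CT", dur, sp,
                          turn_rate = sample(c(-1, 1), 1) *
                            stats::runif(1, 0.02, 0.5)),
        CA = segment_spec("CA", dur, sp,
                          accel = stats::runif(1, -0.5, 0.5)))
    }
    segs
  })
}

#' Circular constant-turn trajectory
#'
#' A single full-turn-rate circle, the canonical single-motion scenario for
#' studying which motion model the tracker selects.
#'
#' @param radius Circle radius in metres.
#' @param speed Speed in m/s.
#' @param duration Total time in seconds.
#' @param base_dt Base sampling interval in seconds.
#' @return A `"trajectory"`.
#' @export
circular_trajectory <- function(radius = 200, speed = 15, duration = 300,
                                base_dt = 0.1) {
  omega <- speed / radius
  generate_trajectory(list(segment_spec("CT", duration, speed,
                                        turn_rate = omega)),
                      base_dt = base_dt)
}

#' Downsample a trajectory to a coarser sampling interval
#'
#' Keeps every k-th sample starting at index 1, where
#' `k = delta_t / base_dt` must be integral. Velocities are recomputed as
#' backward position differences divided by `delta_t`, mirroring how a
#' ranging sensor observes velocity; the first sample's velocity is copied
#' from the second (its backward difference is undefined).
#'
#' @param traj A `"trajectory"`.
#' @param delta_t Target sampling interval in seconds (integer multiple of
#'   `traj$base_dt`).
#' @return A `"trajectory"` at spacing `delta_t`.
#' @export
downsample_trajectory <- function(traj, delta_t) {
  ratio <- delta_t / traj$base_dt
  k <- round(ratio)
  if (abs(ratio - k) > 1e-6 || k < 1) {
    stop("downsample_trajectory: delta_t must be an integer multiple ",
         "of base_dt", call. = FALSE)
  }
  idx <- seq(1, length(traj$times), by = k)
  times <- traj$times[idx]
  pos <- traj$states[idx, c(1, 3), drop = FALSE]
  n <- length(idx)
  states <- matrix(0, n, 4, dimnames = list(NULL, c("x", "vx", "y", "vy")))
  states[, c(1, 3)] <- pos
  if (n >= 2) {
    dv <- diff(pos) / delta_t
    states[2:n, c(2, 4)] <- dv
    states[1, c(2, 4)] <- states[2, c(2, 4)]
  } else {
    states[, c(2, 4)] <- traj$states[idx, c(2, 4)]
  }
  if (k == 1) {
    # identity on positions; keep the analytic velocities
    states[, c(2, 4)] <- traj$states[, c(2, 4)]
  }
  structure(list(times = times, states = states, base_dt = delta_t),
            class = "trajectory")
}

#' Simulation configuration for the scan generator
#'
#' @param delta_t Sampling interval of the scans in seconds.
#' @param delta_l Sensor range resolution in metres; position noise has
#'   variance `4 * delta_l^2` per axis.
#' @param p_fa False-alarm rate: probability that a scan additionally
#'   contains one spurious point.
#' @param fa_radius Radius (m) of the disc, centred on the true position,
#'   in which a false-alarm point is placed uniformly.
#' @param seed Integer seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(delta_t = 1, delta_l = 1, p_fa = 0,
                       fa_radius = 100, seed = 1L) {
  stopifnot(delta_t > 0, delta_l >= 0, p_fa >= 0, p_fa <= 1, fa_radius > 0)
  structure(list(delta_t = delta_t, delta_l = delta_l, p_fa = p_fa,
                 fa_radius = fa_radius, seed = as.integer(seed)),
            class = "sim_config")
}

#' Observe a trajectory through a noisy low-rate scanning sensor
#'
#' Each scan contains the true target point with i.i.d. Gaussian noise of
#' variance `4 * delta_l^2` added independently to x and y. Observed
#' velocities are backward differences of the noisy positions divided by
#' the sampling interval (first frame copies the second). With probability
#' `p_fa` a frame additionally contains one false-alarm point placed
#' uniformly in a disc of radius `fa_radius` around the true position; its
#' velocity observation is differenced against the previous frame's noisy
#' position like any real detection would be. Point order within a frame is
#' randomised; `truth_index` records where the true point landed.
#'
#' @param traj A `"trajectory"` already at the scan spacing `cfg$delta_t`.
#' @param cfg A [sim_config()].
#' @return A list of scan frames; each frame is a list with `time`,
#'   `points` (d x 4 matrix of `[x, vx, y, vy]` observations) and
#'   `truth_index`.
#' @export
observe_trajectory <- function(traj, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (abs(traj$base_dt - cfg$delta_t) > 1e-9) {
    stop("observe_trajectory: trajectory spacing does not match cfg$delta_t",
         call. = FALSE)
  }
  n <- length(traj$times)
  sd_pos <- 2 * cfg$delta_l
  draws <- with_seed(cfg$seed, list(
    noise = matrix(stats::rnorm(2 * n, 0, sd_pos), n, 2),
    has_fa = stats::runif(n) < cfg$p_fa,
    fa_r = cfg$fa_radius * sqrt(stats::runif(n)),
    fa_a = stats::runif(n, 0, 2 * pi),
    truth_first = stats::runif(n) < 0.5
  ))
  noisy <- traj$states[, c(1, 3), drop = FALSE] + draws$noise
  vel <- matrix(0, n, 2)
  if (n >= 2) {
    vel[2:n, ] <- diff(noisy) / cfg$delta_t
    vel[1, ] <- vel[2, ]
  }
  has_fa <- draws$has_fa
  fa_r <- draws$fa_r
  fa_a <- draws$fa_a
  truth_first <- draws$truth_first

  frames <- vector("list", n)
  for (k in seq_len(n)) {
    true_pt <- c(noisy[k, 1], vel[k, 1], noisy[k, 2], vel[k, 2])
    if (has_fa[k]) {
      fx <- traj$states[k, 1] + fa_r[k] * cos(fa_a[k])
      fy <- traj$states[k, 3] + fa_r[k] * sin(fa_a[k])
      if (k >= 2) {
        fv <- (c(fx, fy) - noisy[k - 1, ]) / cfg$delta_t
      } else {
        fv <- c(0, 0)
      }
      fa_pt <- c(fx, fv[1], fy, fv[2])
      if (truth_first[k]) {
        pts <- rbind(true_pt, fa_pt)
        ti <- 1L
      } else {
        pts <- rbind(fa_pt, true_pt)
        ti <- 2L
      }
    } else {
      pts <- rbind(true_pt)
      ti <- 1L
    }
    dimnames(pts) <- list(NULL, c("x", "vx", "y", "vy"))
    frames[[k]] <- list(time = traj$times[k], points = pts,
                        truth_index = ti)
  }
  frames
}

#' Write / read a trajectory as CSV
#'
#' Columns `t, x, y, vx, vy` in SI units, one row per sample. The reader
#' also loads real GPS tracks exported in the same dialect.
#'
#' @param traj A `"trajectory"`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(t = traj$times,
                   x = traj$states[, 1], y = traj$states[, 3],
                   vx = traj$states[, 2], vy = traj$states[, 4])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param path File path of a CSV with header `t,x,y,vx,vy`.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "x", "y", "vx", "vy")
  if (!all(need %in% names(df))) {
    stop("read_trajectory_csv: expected columns t,x,y,vx,vy", call. = FALSE)
  }
  dt <- if (nrow(df) >= 2) df$t[2] - df$t[1] else NA_real_
  states <- cbind(x = df$x, vx = df$vx, y = df$y, vy = df$vy)
  structure(list(times = df$t, states = states, base_dt = dt),
            class = "trajectory")
}

#' Write / read scan frames as CSV
#'
#' Long format with header `t,point_id,x,y,vx,vy,is_truth`; multiple rows
#' share one `t` when a frame holds several candidate points.
#'
#' @param frames List of scan frames from [observe_trajectory()].
#' @param path File path.
#' @export
write_scans_csv <- function(frames, path) {
  rows <- lapply(frames, function(fr) {
    d <- nrow(fr$points)
    data.frame(t = rep(fr$time, d), point_id = seq_len(d),
               x = fr$points[, 1], y = fr$points[, 3],
               vx = fr$points[, 2], vy = fr$points[, 4],
               is_truth = as.integer(seq_len(d) == fr$truth_index))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scans_csv
#' @export
read_scans_csv <- function(path) {
  df <- utils::read.csv(path)
  split_idx <- split(seq_len(nrow(df)), match(df$t, unique(df$t)))
  lapply(split_idx, function(ii) {
    sub <- df[ii, , drop = FALSE]
    pts <- cbind(x = sub$x, vx = sub$vx, y = sub$y, vy = sub$vy)
    ti <- which(sub$is_truth == 1L)
    list(time = sub$t[1], points = pts,
         truth_index = if (length(ti)) ti[1] else -1L)
  })
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards. Keeps simulator draws reproducible without clobbering the
# session's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
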