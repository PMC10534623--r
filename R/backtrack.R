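# Back-tracking correction: a one-step-deep beam over alternative
# measurement associations. At every scan, up to D' candidate points that
# pass the density threshold eta are kept; each live hypothesis is advanced
# with each of its candidates, children are scored by the summed log gate
# density of their last two associations, and the beam is pruned back to D'.
# When the best child at step k+1 descends from an alternative (not the
# primary) association at step k, the previous association is effectively
# revised. Hypotheses are only allowed to disagree on their most recent
# association, so the beam never grows and look-back depth stays at one.

#' Back-tracking configuration
#'
#' @param beam_width Maximum number of live hypotheses D' (>= 1); 1 switches
#'   the mechanism off.
#' @param eta Density threshold for keeping a candidate point (same units
#'   as the gating density, m^-2 on the position marginal). A candidate is
#'   kept while its mixture density is at least `eta`. Large values degrade
#'   to single-candidate tracking; default 0.01.
#' @param relax_if_empty What to do when no candidate passes `eta`:
#'   `"beam"` (default) releases the threshold and keeps up to `beam_width`
#'   top-ranked points, so the correction mechanism stays active when the
#'   prediction spread is wide (low sampling rates); `"argmax"` keeps only
#'   the single most probable point, degenerating to plain tracking;
#'   `FALSE` keeps nothing (the caller must handle an empty gate).
#' @return A list of class `"backtrack_config"`.
#' @export
backtrack_config <- function(beam_width = 2L, eta = 0.01,
                             relax_if_empty = c("beam", "argmax")) {
  stopifnot(beam_width >= 1, eta >= 0)
  if (!isFALSE(relax_if_empty)) {
    relax_if_empty <- match.arg(relax_if_empty)
  }
  structure(list(beam_width = as.integer(beam_width), eta = eta,
                 relax_if_empty = relax_if_empty),
            class = "backtrack_config")
}

new_hypothesis <- function(state, warmup) {
  structure(list(state = state, assoc = integer(0), records = list(),
                 last_logdens = 0, score = 0, warmup = warmup),
            class = "hypothesis")
}

# Per-model predictions/covariances and per-point mixture densities for one
# hypothesis facing one frame.
frame_densities <- function(state, frame, bank, cfg) {
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
  dens <- vapply(seq_len(nrow(frame$points)), function(i) {
    mixture_density(frame$points[i, ], preds, S_preds, state$mu, cfg)
  }, numeric(1))
  list(preds = preds, S_preds = S_preds, dens = dens)
}

#' Gate candidate points for one hypothesis
#'
#' Candidates are ranked by mixture density (descending), kept while the
#' density is at least `eta`, and truncated to the beam width. If nothing
#' passes, the threshold is released per `relax_if_empty` (see
#' [backtrack_config()]).
#'
#' @param frame A scan frame.
#' @param hyp A hypothesis (from the beam) or a bare `"tracker_state"`.
#' @param bank The model bank.
#' @param cfg A [tracker_config()].
#' @param bt_cfg A [backtrack_config()].
#' @return A data frame with columns `index` and `density`, ranked.
#' @export
gate_candidates <- function(frame, hyp, bank, cfg, bt_cfg) {
  state <- if (inherits(hyp, "hypothesis")) hyp$state else hyp
  fd <- frame_densities(state, frame, bank, cfg)
  ord <- order(fd$dens, decreasing = TRUE)
  keep <- ord[fd$dens[ord] >= bt_cfg$eta]
  keep <- utils::head(keep, bt_cfg$beam_width)
  if (length(keep) == 0L && !isFALSE(bt_cfg$relax_if_empty)) {
    keep <- if (identical(bt_cfg$relax_if_empty, "argmax")) {
      ord[1]
    } else {
      utils::head(ord, bt_cfg$beam_width)
    }
  }
  data.frame(index = keep, density = fd$dens[keep])
}

#' Expand the hypothesis beam by one scan and prune it
#'
#' Every (hypothesis, gated candidate) pair is advanced one tracker step;
#' children are scored by the summed log gate density of their last two
#' associations, and the top `beam_width` children survive, best first.
#' Before expansion, hypotheses that disagree with the current primary
#' anywhere except their most recent association are dropped, which keeps
#' the look-back depth at exactly one step.
#'
#' @param hyps Non-empty list of hypotheses (element 1 need not be best).
#' @param frame The next scan frame.
#' @param bank The model bank.
#' @param cfg A [tracker_config()].
#' @param bt_cfg A [backtrack_config()].
#' @return A list of at most `beam_width` hypotheses, best first.
#' @export
expand_and_prune <- function(hyps, frame, bank, cfg, bt_cfg) {
  stopifnot(length(hyps) >= 1)
  scores <- vapply(hyps, `[[`, numeric(1), "score")
  primary <- hyps[[which.max(scores)]]
  len <- length(primary$assoc)
  if (len >= 1L && length(hyps) > 1L) {
    committed <- primary$assoc[seq_len(len - 1L)]
    hyps <- Filter(function(h) {
      identical(h$assoc[seq_len(len - 1L)], committed)
    }, hyps)
  }
  children <- list()
  for (h in hyps) {
    cand <- gate_candidates(frame, h, bank, cfg, bt_cfg)
    for (i in seq_len(nrow(cand))) {
      out <- track_step(h$state, frame, bank, cfg,
                        forced_index = cand$index[i])
      logd <- log(max(cand$density[i], 1e-300))
      child <- h
      child$state <- out$state
      child$assoc <- c(h$assoc, cand$index[i])
      child$records <- c(h$records, list(out$record))
      child$score <- h$last_logdens + logd
      child$last_logdens <- logd
      children[[length(children) + 1L]] <- child
    }
  }
  ord <- order(vapply(children, `[[`, numeric(1), "score"),
               decreasing = TRUE)
  children[utils::head(ord, bt_cfg$beam_width)]
}

#' Extract the best hypothesis's track
#'
#' @param hyps Non-empty list of hypotheses.
#' @return The `"track_result"` of the highest-scoring hypothesis, with its
#'   (possibly revised) association history.
#' @export
finalize <- function(hyps) {
  stopifnot(length(hyps) >= 1)
  scores <- vapply(hyps, `[[`, numeric(1), "score")
  best <- hyps[[which.max(scores)]]
  res <- build_track_result(best$records, n_models = best$state$n,
                            warmup = best$warmup)
  res$assoc <- best$assoc
  res
}

#' Track a scan sequence with back-tracking correction
#'
#' Same interface as [track()], but measurement association runs through
#' the one-step-deep hypothesis beam, allowing the previous association to
#' be revised when the following scan contradicts it. With `beam_width = 1`
#' or false-alarm-free scans the output is identical to [track()].
#'
#' @param frames List of scan frames.
#' @param bank The model bank.
#' @param cfg A [tracker_config()].
#' @param bt_cfg A [backtrack_config()].
#' @return A `"track_result"` (with the chosen association history in
#'   `$assoc`).
#' @export
track_backtrack <- function(frames, bank, cfg = tracker_config(),
                            bt_cfg = backtrack_config()) {
  L <- cfg$window_len
  state <- init_track(frames, cfg, bank)
  beam <- list(new_hypothesis(state, warmup = L + 1))
  steps <- frames[-(seq_len(L + 1))]
  for (k in seq_along(steps)) {
    beam <- expand_and_prune(beam, steps[[k]], bank, cfg, bt_cfg)
  }
  finalize(beam)
}
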