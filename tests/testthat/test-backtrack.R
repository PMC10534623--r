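test_that("candidate gating thresholds, truncates and relaxes", {
  cfg <- tracker_config()
  bank <- cv_bank()
  sc_tr <- downsample_trajectory(
    generate_trajectory(list(segment_spec("CV", 40, 12)), 0.1), 1)
  fr <- observe_trajectory(sc_tr, sim_config(delta_t = 1, delta_l = 1,
                                             p_fa = 0, seed = 2))
  st <- init_track(fr, cfg, bank)
  next_fr <- fr[[9]]
  # single in-gate point is kept
  cand <- gate_candidates(next_fr, st, bank, cfg,
                          backtrack_config(eta = 1e-6))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$index, 1L)
  # construct a frame with three points of decreasing plausibility
  truth <- next_fr$points[1, ]
  frame3 <- next_fr
  frame3$points <- rbind(truth, truth + c(8, 0, 8, 0),
                         truth + c(60, 0, 60, 0))
  bt <- backtrack_config(beam_width = 2, eta = 1e-6)
  cand3 <- gate_candidates(frame3, st, bank, cfg, bt)
  expect_lte(nrow(cand3), 2L)             # truncated at D'
  expect_equal(cand3$index[1], 1L)        # ranked by density
  expect_true(all(diff(cand3$density) <= 0))
  # threshold + truncation arithmetic on given densities
  dens <- cand3$density
  expect_true(all(dens >= 1e-6))
  # nothing passes a huge eta: relaxation keeps the beam (default) or the
  # single argmax
  cand_beam <- gate_candidates(frame3, st, bank, cfg,
                               backtrack_config(beam_width = 2, eta = 1e6))
  expect_equal(nrow(cand_beam), 2L)
  cand_one <- gate_candidates(frame3, st, bank, cfg,
                              backtrack_config(beam_width = 2, eta = 1e6,
                                               relax_if_empty = "argmax"))
  expect_equal(nrow(cand_one), 1L)
  expect_equal(cand_one$index, 1L)
})

test_that("a degenerate beam reproduces plain tracking", {
  cfg <- tracker_config()
  tr <- downsample_trajectory(piecewise_scenario(31, duration = 80), 2)
  fr <- observe_trajectory(tr, sim_config(delta_t = 2, delta_l = 1,
                                          p_fa = 0.1, seed = 4))
  plain <- track(fr, cv_bank(), cfg)
  beam1 <- track_backtrack(fr, cv_bank(), cfg,
                           backtrack_config(beam_width = 1))
  expect_equal(beam1$est, plain$est, tolerance = 1e-12)
  expect_equal(beam1$chosen, plain$chosen)
})

test_that("without false alarms back-tracking changes nothing", {
  cfg <- tracker_config()
  tr <- downsample_trajectory(piecewise_scenario(32, duration = 80), 3)
  fr <- observe_trajectory(tr, sim_config(delta_t = 3, delta_l = 1,
                                          p_fa = 0, seed = 6))
  plain <- track(fr, cv_bank(), cfg)
  bt <- track_backtrack(fr, cv_bank(), cfg, backtrack_config())
  expect_equal(bt$est, plain$est, tolerance = 1e-12)
  expect_equal(bt$assoc, rep(1L, length(bt$assoc)))
})

test_that("the beam stays bounded and hypotheses share old history", {
  cfg <- tracker_config()
  tr <- downsample_trajectory(piecewise_scenario(33, duration = 100), 2)
  fr <- observe_trajectory(tr, sim_config(delta_t = 2, delta_l = 1,
                                          p_fa = 0.3, fa_radius = 40,
                                          seed = 9))
  bt_cfg <- backtrack_config(beam_width = 2, eta = 1e-9)
  st <- init_track(fr, cfg, cv_bank())
  beam <- list(immgru:::new_hypothesis(st, warmup = 8))
  for (k in 9:length(fr)) {
    beam <- expand_and_prune(beam, fr[[k]], cv_bank(), cfg, bt_cfg)
    expect_lte(length(beam), 2L)
    if (length(beam) == 2L) {
      a <- beam[[1]]$assoc
      b <- beam[[2]]$assoc
      # hypotheses may disagree on the newest association and on the one
      # still open to revision, but never deeper than that
      keep <- seq_len(max(0, length(a) - 2))
      expect_equal(a[keep], b[keep])
    }
  }
  res <- finalize(beam)
  expect_equal(length(res$assoc), length(fr) - 8)
})

test_that("a transient false selection is revised one step later", {
  # constructed two-point scenario: at step k the false point sits slightly
  # closer to the prediction than the true point, but the step-k+1 scan is
  # only consistent with the true history.
  cfg <- tracker_config()
  tr <- downsample_trajectory(
    generate_trajectory(list(segment_spec("CV", 40, 12)), 0.1), 1)
  fr <- observe_trajectory(tr, sim_config(delta_t = 1, delta_l = 0.5,
                                          p_fa = 0, seed = 12))
  clean <- track(fr, cv_bank(), cfg)
  k <- 15
  step_idx <- k - 8
  # decoy placed exactly at the combined prediction for frame k, with a
  # corrupted velocity: it wins the position gate but poisons the history
  decoy <- clean$pred[step_idx, ] + c(0, 3, 0, -3)
  true_pt <- fr[[k]]$points[1, ]
  fr[[k]]$points <- rbind(decoy, true_pt)
  fr[[k]]$truth_index <- 2L
  plain <- track(fr, cv_bank(), cfg)
  expect_equal(plain$chosen[step_idx], 1L)  # plain tracker takes the bait
  bt <- track_backtrack(fr, cv_bank(), cfg,
                        backtrack_config(beam_width = 2, eta = 0))
  # one scan later the surviving hypothesis descends from the true point
  expect_equal(bt$assoc[step_idx], 2L)
  expect_lte(bt$n_false_selected, plain$n_false_selected)
})

test_that("finalize returns the highest-probability hypothesis", {
  st <- list(n = 1L)
  h1 <- immgru:::new_hypothesis(structure(st, class = "tracker_state"), 8)
  h2 <- h1
  h1$score <- -5
  h2$score <- -9
  rec <- list(time = 1, pred = rep(0, 4), est = rep(1, 4), mu = 1,
              chosen = 1L, density = 0.1, truth_index = 1L,
              n_points = 1L)
  h1$records <- list(rec)
  h2$records <- list(within <- rec)
  h2$records[[1]]$est <- rep(9, 4)
  expect_equal(finalize(list(h2, h1))$est[1, ], rep(1, 4))
})
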