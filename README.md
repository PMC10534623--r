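# immgru

Tracking small, manoeuvring airborne targets — birds observed by a
scanning Lidar — when the sensor refresh rate is low (sampling intervals
Δt up to 5 s) and scans contain occasional false-alarm points that are
indistinguishable from the target.

The tracker maintains a bank of *n* small bidirectional GRU motion
models, each trained on trajectories resampled within one band of
sampling intervals, and fuses them with an interacting-multiple-model
(IMM) mechanism. At each scan, model *j* predicts the next state
`X_{k+1/k}^j` from the last *L* (estimate, measurement) pairs; the
prediction is converted to an approximate linear transition

    F = α F_CV(T) + (1 − α) F_CT(T, Ω),   α = argmin ‖F X̂_k − X_{k+1/k}‖²

so that covariances propagate as `S_{k+1/k} = F S_k F' + Q`. Candidate
scan points are gated by the mixture density
`Σ_j μ_j N(z; H X_{k+1/k}^j, H S_{k+1/k}^j H' + R)`, each model runs a
Kalman update, and model probabilities follow Bayes' rule,
`μ' ∝ μ · likelihood`. A one-step-deep back-tracking beam (width D′,
density threshold η) revises the previous measurement association when
the next scan contradicts it. Classical baselines (UKF with augmented
turn rate, IMM-UKF, bootstrap particle filter, single-model GRU-EKF), a
trajectory/scan simulator and a Monte-Carlo evaluation harness are
included; the GRU forward/backward passes and the Adam optimiser are
implemented in plain R.

## Worked example

Train a small two-band bank, then track a noisy piecewise-manoeuvring
trajectory sampled every 2 s with 5% false alarms:

```r
library(immgru)

trajs <- lapply(1:4, function(i) piecewise_scenario(i, duration = 120))
bank <- build_bank(trajs, n_models = 2, gru_config(),
                   train_config(max_epochs = 60, seed = 1),
                   sim_config(delta_l = 1, seed = 2),
                   max_windows_per_bin = 1500)

truth <- downsample_trajectory(piecewise_scenario(99, duration = 120), 2)
scans <- observe_trajectory(truth, sim_config(delta_t = 2, delta_l = 1,
                                              p_fa = 0.05, seed = 3))
res <- track_backtrack(scans, bank, tracker_config(),
                       backtrack_config())

aligned <- truth$states[-(1:8), ]
cat(sprintf("estimation RMSE: %.2f m\n", rmse(res, aligned)))
cat(sprintf("prediction RMSE: %.2f m\n", rmse(res, aligned, "prediction")))
cat(sprintf("false detections: %d of %d false alarms\n",
            res$n_false_selected, res$n_false_present))
print(round(weight_statistics(res), 3))
```

```
estimation RMSE: 3.19 m
prediction RMSE: 19.23 m
false detections: 0 of 3 false alarms
[1] 0.599 0.401
```

The estimation error sits just above the sensor noise floor (position
noise has variance 4 m², i.e. ~2.8 m RMS over two axes), the one-step
prediction error reflects how much the target can manoeuvre in 2 s, no
false-alarm point survived the mixture gate, and the model trained on the
slower half of the sampling range carries the larger share of the
probability weight at Δt = 2 s.

A thin command-line wrapper over the same functions lives in
`inst/cli/immgru.R` (`simulate`, `track`, `evaluate`).

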