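---
title: "Tracking manoeuvring birds at low scan rates: the IMM-GRU method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking manoeuvring birds at low scan rates: the IMM-GRU method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immgru)
```

## The problem

Scanning Lidar is attractive for bird surveillance around airports: it
resolves small, low-flying targets that microwave radar misses. Photon
counting, however, forces long dwell times, so the scan refresh rate is
low — the interval between successive observations of one bird, `Δt`, can
reach several seconds. Over such an interval a bird may change its motion
several times, so no single kinematic model (constant velocity, constant
turn) describes the transition between scans, and classical filters built
on such models degrade quickly as `Δt` grows. On top of that a small bird
is a single point on the scan, indistinguishable from a background
false-alarm point, so the tracker must also decide *which* point in each
scan is the bird.

The planar state at scan `k` is `X_k = [x, vx, y, vy]` (metres, m/s). The
sensor measures positions only; observed velocity is the backward
difference of two adjacent observed positions, so the measurement
`Z_k = [x°, vx°, y°, vy°]` is the full state through an identity
measurement matrix `H`, with strongly correlated noise between the
position and velocity channels.

## The method

The tracker runs `n` small recurrent motion models in parallel and fuses
them with an interacting-multiple-model (IMM) mechanism. One cycle per
scan:

1. **Trajectory prediction.** Each model `j` is a stacked bidirectional
   GRU that consumes the last `L` rows of `concat(X̂_k^j, Z_k)` — its own
   estimate history spliced with the shared measurement history — and
   outputs the normalised next state through an affine + `tanh` head,
   which is then denormalised to the absolute prediction `X_{k+1/k}^j`.
2. **Approximate state-transfer matrix.** A network prediction is a bare
   point; covariance propagation and likelihood evaluation need a linear
   transition. We fit `F = α F_CV(T) + (1−α) F_CT(T, Ω)` with
   `α ∈ [0, 1]` minimising `‖F X̂_k^j − X_{k+1/k}^j‖²` (a one-dimensional
   quadratic, solved in closed form and clipped), then propagate
   `S_{k+1/k}^j = F S_k^j F' + Q`.
3. **Noise filtering.** Candidate scan points are scored by the mixture
   density `Σ_j μ_k^j N(z; H X_{k+1/k}^j, H S_{k+1/k}^j H' + R)` and the
   argmax point becomes the measurement.
4. **State estimation.** A standard Kalman update per model.
5. **Model probabilities.** `μ_{k+1}^j ∝ μ_k^j · N(z; H X_{k+1/k}^j,
   H S_{k+1/k}^j H' + R)` — pure Bayes, no Markov mixing between steps —
   optionally clamped below by a floor.
6. **Combination.** Output estimate and prediction are the
   probability-weighted means.

Specialisation across the bank comes entirely from training data: the
sampling-interval range 0.1–5 s is split into `n` contiguous bands
(`delta_t_bins()`; with `n = 5`: `[0.1,1], [1.1,2], [2.1,3], [3.1,4],
[4.1,5]`), and model `j` is trained only on trajectories resampled at
intervals in band `j`. `Δt` is *not* an input feature.

### Back-tracking correction

A false-alarm point that wins the gate corrupts the next `L` windows. The
correction keeps, at each scan, up to `D′` candidate points whose mixture
density is at least `η`, advances every live hypothesis with each of its
candidates, scores children by the summed log gate density of their last
two associations, and prunes back to `D′`. If the best hypothesis one scan
later descends from an *alternative* association, the previous association
is revised. Hypotheses may disagree only on their most recent association
(look-back depth one): two consecutive false selections occur with
probability below `P_fa²` and are not worth the exponential bookkeeping.

One subtlety: with the default noise settings the position-marginal
mixture density peaks around `1/(2π·30) ≈ 0.005 m⁻²` at `Δt ≥ 2` s, below
the default threshold `η = 0.01`. A gate that kept only the single argmax
point whenever nothing passes `η` would therefore never retain
alternatives at exactly the sampling intervals the mechanism exists for.
Releasing the threshold (`relax_if_empty = "beam"`, the default) keeps up
to `D′` ranked candidates in that case; the strict single-point behaviour
is available as `relax_if_empty = "argmax"`.

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `R` | `4 I₄` | m², m²/s² | measurement noise; matches position noise of variance 4 m² (`δl = 1` m) |
| `Q` | `16 I₄` | m², m²/s² | process noise; deliberately large so the filter re-converges quickly after a motion change |
| `L` | 7 | scans | history window fed to the motion models |
| `mu_floor` | 1e-3 | — | lower clamp on model probabilities; 0 allows full Bayes saturation (used in the regime-identification experiment) |
| `n_models` | 5 | — | bank size; bands tile 0.1–5 s |
| `D′` (`beam_width`) | 2 | — | live hypotheses in the back-tracking beam |
| `η` (`eta`) | 0.01 | m⁻² | density threshold for keeping gate candidates |
| hidden size | 32 | — | GRU feature dimension; 2 stacked bidirectional layers, dropout 0.1 between them |
| batch / lr / decay | 256 / 0.01 / 0.5 | — | Adam with decoupled weight decay; cosine-annealed learning rate restarting every 5 epochs; early stopping at patience 20. The 0.5 decay is the protocol value and is unusually large — 1e-2 is a reasonable fallback |
| `v_max` | 30 | m/s | normalisation speed scale; positions are divided by `v_max · L · Δt_max` of the band |

Gating and likelihood densities use the 2-D position marginal by default
(`gate_full = FALSE`): the differenced velocity channels are deterministic
functions of adjacent positions, so a full 4-D density would double-count
the same noise.

## Design choices where the design was open

- **Turn rate `Ω` for the CT member.** Estimated each step from the
  wrapped heading change of the model's last two estimates
  (`estimate_turn_rate()`). A joint grid search over `(α, Ω)` would also
  work; the heading estimate is cheaper and unbiased on turns.
- **Blend degeneracy.** When `F_CV X̂ = F_CT X̂` (stationary target or
  `Ω = 0`), `α = 1`: the simpler model wins ties.
- **Normalisation.** Window-relative displacement coordinates: subtract
  the newest estimated position, divide positions by
  `v_max · L · Δt_max` and velocities by `v_max`. This makes the network
  translation-invariant and keeps well-behaved targets inside the `tanh`
  head's `(−1, 1)` range. Targets are normalised identically.
- **Teacher forcing.** During training the estimate channel carries
  ground-truth states; closed-loop estimates appear only at tracking
  time. This keeps the supervised targets stable.
- **Sequence read-out.** The head consumes the last time-step of the top
  layer (standard sequence-to-one); pooling over steps is a possible
  alternative that we did not find necessary.
- **Warm start.** A constant-velocity Kalman filter runs over the first
  `L + 1` scans to fill the history window; it starts from covariance
  `R`, and the per-model covariances continue from its final posterior.
  With a bank of one analytic CV predictor the whole loop is then
  *algebraically identical* to a textbook CV Kalman filter — the test
  suite pins this to 1e-9.
- **Model-probability likelihood.** The textbook-circular alternative
  (scoring the measurement against the *posterior* it just produced) is
  replaced by the standard predictive likelihood centred on
  `H X_{k+1/k}^j` with innovation covariance; with `H = I` the added `R`
  only widens gates, which is the safe direction.
- **Empty scans.** The combined prediction is carried forward as a
  pseudo-measurement under `10 R`.

## The simulator

`generate_trajectory()` concatenates analytic constant-velocity,
constant-turn and constant-acceleration segments (position and heading
continuous across joins) at a 0.1 s base interval. The scan model
(`observe_trajectory()`) then emulates the data-preparation protocol:
downsampling to `Δt ∈ [0.1, 5]` s with velocities recomputed as backward
differences, i.i.d. Gaussian position noise of variance `4 δl²` per axis
with `δl ∈ [0.5, 3]` m held constant per run (no target–sensor geometry
is modelled, so range-dependent resolution is left off), and, with
probability `p_fa ≤ 5%`, one false-alarm point placed uniformly in a disc
of radius 100 m around the true position — near enough to be confusable
with the target, which is the premise of the gating problem. Pigeon-like
defaults: speeds 10–20 m/s, turn rates up to 0.5 rad/s, segment durations
5–60 s.

What the simulator does **not** reproduce: real pigeon GPS tracks
(smoothly varying accelerations, wind response, flock interactions),
altitude, photon-level Lidar physics, or range-dependent resolution.
Passing tests therefore demonstrate the mechanics of the method — regime
identification, gating, correction, degradation with `Δt` — under
controlled kinematics, not field performance on real birds.

## Problem sizes and numerical choices

All tests and the acceptance script run at desk scale, chosen as the
smallest sizes at which the studied effects are stable: banks are trained
on 8 synthetic trajectories of ~150 s (up to 3000 windows per band, batch
256, at most 150 epochs under 20-epoch patience), tracking experiments
use 50–200 Monte-Carlo replicates, and the Monte-Carlo noise-calibration
checks use 1e5 draws. Singular innovation covariances are
ridge-regularised with `1e-9 I`; propagated covariances are symmetrised;
hypothesis log-densities are floored at `log(1e-300)`; turn rates below
1e-8 rad/s use the analytic CV limit of the CT matrix. Every stochastic
component (simulator, training, particle filter) is seeded and
reproducible; the simulator restores the caller's RNG state.

## Known limitations

- Single-target tracking only: no track initiation/termination and no
  joint data association across multiple birds.
- The bank must be trained for the sampling-interval range it will see;
  a scan rate outside 0.1–5 s needs retraining.
- Desk-scale training produces serviceable but not converged networks;
  prediction RMSE (though not the qualitative behaviour) improves with
  more trajectories and epochs.
- The classical baselines (UKF, IMM-UKF, PF, GRU-EKF) use conventional
  but necessarily chosen internals (model sets, transition matrices,
  sigma-point spreads); comparisons against them characterise this
  implementation, not any published numbers.
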