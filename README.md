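# gaitmodes

Task-dependent and task-independent subspace analysis of neural population
activity during locomotion.

## The problem

During walking, climbing, or obstacle avoidance, sensorimotor cortical
populations fire in patterns locked to the gait cycle. Across different
locomotor tasks the same population reuses part of its activity — a
*task-independent* (TI) temporal scaffold tied to gait phase — and
reorganizes the rest — *task-dependent* (TD) structure specific to each
task. `gaitmodes` is for researchers analyzing multi-channel firing-rate
recordings aligned to gait events who want to quantify this split and how
it propagates between cortical regions.

The package implements the full analysis chain:

* **Peri-gait tensors** — spike-rate estimation (10 ms sliding counts,
  Gaussian smoothing with 50 ms s.d., per-channel z-scoring, 1 kHz),
  cycle rejection (duration > 1.5 s; stance duration outside
  `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` per task), and time-warping of every gait
  cycle to a 100-sample phase grid (stance = samples 0–59, swing = 60–99).
* **Single-channel statistics** — preferred gait phase (PGP), modulation
  depth, cross-task correlation, circular s.d. of the PGP across tasks
  (angular deviation `sqrt(2(1 − R̄))`, degrees).
* **Manifolds** — PCA dimensionality (smallest number of modes whose
  cumulative variance strictly exceeds 90%), channel-subsampled
  single-task / all-task / leave-one-out batteries, and the alignment
  index `AI = (‖X‖² − ‖X − D_m E_m X‖²)/‖X‖²` between task manifolds.
* **Demixed PCA** — decomposition of the trial-averaged tensor into
  gait-phase (TI) and task (TD) marginalizations,
  `X = X_TI + X_TD`, with per-mode losses `‖X_θ − F_θ D_θ X‖²` minimized
  in closed form, modes labeled TI/TD by their dominant (>50%) variance
  part, exact variance accounting, and mode removal from full-resolution
  rates.
* **Communication subspaces** — ridge regression `B = (XᵀX + λI)⁻¹XᵀY`
  from a source to a target region (10-fold CV over whole gait cycles,
  one-SE rule for λ), reduced-rank restriction
  `B_RRR(m) = B_RIDGE V_m V_mᵀ`, rank `m_RRR` at 95% of the ridge
  predictor's explained variance, and the communication basis from the
  leading columns of `B̄ = B_RIDGE V`.
* **Subspace geometry** — principal angles (arc-cosines of the singular
  values of `W_aᵀW_b`) and the Δangles statistic (mean angle to the 5
  leading TD modes minus mean angle to the 5 leading TI modes; positive =
  TI-aligned communication).
* **Nulls** — bootstrap pseudo-datasets, uniform phase shuffling,
  Haar-random subspaces, and one-sided Monte-Carlo permutation p-values
  with the add-one convention (`p = (1 + #extreme)/(1 + N)`, floor
  1/2001 at N = 2000).
* **Decoders** — regularized-LDA gait-event detection (0.80 posterior
  threshold, 100 ms refractory period, F-score over foot-strike and
  foot-off), rLDA task classification, and Wiener-filter reconstruction of
  EMG envelopes (100 ms window) and kinematics (300 ms window) with
  Savitzky–Golay velocities.
* **Synthetic sessions** — a generator that plants TI/TD latent subspaces
  with an exact variance split, a low-rank inter-region communication map
  with controlled TI/TD alignment, and linear EMG/kinematic readouts, so
  every statistic above has a known ground truth.

## Worked example

The `analysis/` scripts run the whole chain on a synthetic session
(5 tasks × 60 cycles, 32 channels, planted TI fraction 0.68, planted rank-3
TI-aligned communication map):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/04_dpca.R
Rscript analysis/05_communication.R
Rscript analysis/06_principal_angles.R
Rscript analysis/07_decoding.R
```

which prints (abridged):

```
Planted TI variance fraction 0.68 (realized in time domain: 0.683)
Task-independent subspace: 68.1% of explained variance (planted fraction: 68%).
  task 1: m_RRR = 3, ridge R2 = 0.949           # planted rank recovered
Delta angles per task: 72.4, 72.6, 72.2, 71.8, 72.3 (mean 72.3 deg).
Cross-task gait-event F-scores (calibrated on task 1):
          removed  k removed_variance  f_score
             none  0             0.00     0.92
 task-independent  2             0.22     0.78
 task-independent  6             0.66     0.37   # TI removal breaks generalization
   task-dependent  2             0.10     0.94
   task-dependent 14             0.32     0.94   # TD removal does not
```

Read together: the demixed decomposition recovers the planted 68% TI
variance share; reduced-rank regression recovers the planted rank-3
communication map in every task, and its subspace is aligned with the TI
subspace (Δangles ≫ 0, chance 0.2 ± 6.1°) exactly as planted; and the
cross-task-generalizing temporal code lives in the TI subspace — removing
it degrades gait-event decoding on unseen tasks progressively while
removing the (larger-dimensional) TD subspace leaves decoding untouched.

The methods vignette (`vignettes/methods.Rmd`) documents the models, the
parameter choices, the generator's design, and its limitations.

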