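---
title: "Subspace analysis of peri-gait neural population activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subspace analysis of peri-gait neural population activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmodes)
```

## The scientific problem

During locomotion, cortical population activity is phase-locked to the gait
cycle, yet the same neurons participate in many different locomotor tasks
(corridor walking, ladder, stairs, obstacles, treadmill). A central question
is how much of the population activity is *task-independent* (TI) — a common
temporal scaffold tied to the gait phase that is shared across tasks — and
how much is *task-dependent* (TD), reorganizing with the demands of each
task. A second question is which of these two components one region
*communicates* to another. `gaitmodes` implements the complete analysis
chain for these questions on multi-channel firing-rate recordings aligned
to gait events, together with a synthetic-session generator that plants
known latent structure so that every statistic in the chain has a
recoverable ground truth.

## Pre-processing and the peri-gait tensor

Firing rates are estimated from spike times by counting spikes in sliding
10 ms windows stepped at 0.5 ms (2000 Hz), scaling to Hz, smoothing with a
Gaussian kernel (50 ms s.d.), z-scoring each channel over the session, and
decimating to 1000 Hz (every second sample; the smoothing already
bandlimits the signal, so no further anti-alias filter is applied).
Channels with zero variance are kept in containers but flagged and excluded
from every analysis, which avoids divide-by-zero artifacts without silent
shape changes.

A gait cycle is the epoch between two consecutive foot strikes; the foot-off
divides it into stance and swing. Cycles longer than 1.5 s are rejected, and
cycles whose stance duration falls outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`
are rejected as outliers. The IQR rule is applied *per task*, after the
duration rule, because tasks have systematically different duration
distributions; applying it across tasks would preferentially discard cycles
of the slowest task. Each surviving cycle is linearly resampled so that
stance occupies phase samples 0–59 and swing samples 60–99 (0-based;
intervals are half-open `[start, end)`). Linear interpolation cannot create
new extrema, so warping preserves each cycle's peak rate and modulation
depth. The result is the peri-gait tensor: channels × tasks × cycles × 100.

Phases are treated as circular with period 100; degrees are phase × 3.6.
The preferred gait phase (PGP) of a channel is the circular argmax of its
trial-averaged peri-gait rate (ties broken to the smallest sample index).
The circular standard deviation uses the angular-deviation form
`sqrt(2 (1 - Rbar))` reported in degrees; this convention reproduces the
chance level of ~60.3° for five uniformly drawn angles, which anchors the
chance line of the PGP-stability analysis. The logarithmic form
`sqrt(-2 ln Rbar)` is available via `circ_sd(form = "log")` but diverges
for dispersed samples and is not used for reported values.

## Manifold dimensionality and the alignment index

Dimensionality is the smallest number of leading principal components whose
cumulative variance *strictly* exceeds 90% (the threshold is configurable;
conclusions should be checked at 80–95%). A guard of 1e-9 on the strict
comparison keeps spectra that sit exactly on the boundary in exact
arithmetic (e.g. ten equal eigenvalues at a 0.9 threshold) from being
tipped by floating-point rounding.

PCA for dimensionality operates on *single-cycle* warped activity
concatenated across cycles, not on trial averages: the ceiling argument —
the largest measurable dimensionality is roughly the cycle duration divided
by the smoothing-filter width (`dimensionality_ceiling(942, 128)` = 7.4) —
reasons about single-cycle activity, and trial averaging would deflate
noise dimensions unevenly across tasks with different cycle counts.

When regions with different channel counts are compared, all quantities are
means over repeated random draws of 32 channels. The implementation
precomputes per-task second-moment matrices once, so each channel draw
reduces to an eigendecomposition of a submatrix; this makes thousands of
draws cheap and is verified in the tests against direct PCA on the
concatenated data.

The alignment index between tasks a and b projects task a's mean peri-gait
activity into task b's m-dimensional manifold and measures the captured
variance via the reconstruction-error form
`AI = (||X||^2 - ||X - D_m E_m X||^2) / ||X||^2`. Two normalizations are
implemented because the quantity is used in two roles: `normalize = "self"`
(the default for the session statistic) divides by the variance captured in
task a's own m-dimensional manifold, and `normalize = "none"` returns the
raw captured fraction, which is the form whose null against a Haar-random
m-dimensional manifold equals m/n for isotropic n-dimensional data. The
common dimension m defaults to the larger of the two tasks' 90%
dimensionalities so that numerator and denominator always use the same m;
per-task m is available through the `m` argument.

## Demixed PCA: task-independent and task-dependent subspaces

The mean-centered trial-averaged tensor X (channels × tasks × 100) is split
into exactly two marginalizations: the gait-phase part
`X_TI[channel, phase] = mean over tasks` (replicated across tasks) and the
remainder `X_TD = X - X_TI`. Only two marginalizations are used — gait
phase and task — rather than the four-way split of generic two-factor
demixed PCA, because phase and task are the only behavioral parameters in
this design. The split is exactly orthogonal
(`||X||^2 = ||X_TI||^2 + ||X_TD||^2`), which the tests assert on random
tensors.

Per marginalization θ the loss `||X_θ - F_θ D_θ X||^2` is minimized in
closed form: a ridge regression of X_θ on X (regularizer
μ = 1e-6 ||X||²/n by default — trial-averaged data is well conditioned, so
a cross-validated μ is not implemented) followed by projection onto the
leading left singular vectors of the fitted prediction. Ten modes per
marginalization are retained by default (capped at the data rank), pooled,
and ordered by total explained variance. Decoder axes are normalized to
unit length and encoders carry the least-squares reconstruction scale, so
each mode's rank-1 image of the data is invariant to the normalization
convention; the tests verify each mode against a brute-force
pseudoinverse-plus-SVD oracle.

Each mode's explained variance splits additively into its TI and TD
contributions; a mode is labeled task-independent iff the TI part accounts
for more than 50% of its variance. The TI *subspace variance* reported as
the headline number is the variance summed over TI-labeled modes as a share
of the total explained by all modes; the marginalization totals
(`||X_TI||^2 / ||X||^2`) are reported alongside as the pie-chart totals.
On planted data the two agree to within the noise floor.

Mode removal deflates the full-resolution rate matrix sequentially
(`X <- X - f_j d_j' X`), not only the trial averages, and reports the
removed variance fraction so decoding outcomes can be related to the amount
of removed variance. Because the pooled modes are not mutually orthogonal,
sequential deflation is order-dependent; the canonical order (all TI modes
in ranking order, then all TD modes) is used for the decomposition residual
so that removing both labels reproduces it exactly.

## Communication subspaces

For a single task, the samples are the concatenated 100-sample warped
cycles; the source matrix X (samples × p) predicts the target matrix Y
(samples × q) through ridge regression
`B = (X'X + λI)^{-1} X'Y`. The grid spans 1e-4 to 1e4 times the mean
diagonal of X'X (20 log-spaced points); λ* is chosen by 10-fold
cross-validation with the one-standard-error rule — the largest λ whose
mean held-out R² is within one SE of the best. Folds are contiguous blocks
of whole gait cycles, never random samples, because samples within a cycle
are strongly autocorrelated and random folds would leak.

The rank restriction projects the ridge prediction onto its top-m principal
components: `B_RRR(m) = B_RIDGE V_m V_m'`. The retained rank m_RRR is the
smallest m whose prediction explains at least 95% of the variance explained
by the full ridge predictor. The multi-output R² is pooled
(`1 - Var(Y - Yhat)/Var(Y)`), and the R²(m) curve is provably
non-decreasing in m (the per-component gain works out to
`v'(Yhat'Yhat + 2λB'B)v ≥ 0`), which the tests assert on arbitrary inputs.
The first m_RRR columns of `Bbar = B_RIDGE V` span the communication
subspace in source-channel space; they are orthonormalized (SVD) before any
principal-angle computation since their conditioning is otherwise
unconstrained.

## Principal angles, Δangles, and the null machinery

Principal angles between two orthonormal bases are the arc-cosines of the
singular values of `W_a' W_b`, clipped to [0°, 90°]. The Δangles statistic
is the mean angle between the communication subspace and the 5 leading TD
modes minus the mean angle to the 5 leading TI modes; exactly five modes
per label are required (an informative error names any shortfall), because
principal angles are sensitive to subspace dimensionality. Positive Δ means
TI-aligned communication.

The `null_engine` provides the six resampling/randomization schemes the
analyses use: two- and five-fold bootstrap pseudo-datasets of cycles
(treated as pseudo-tasks, for noise ceilings of the correlation, alignment,
PGP-s.d. and TI-variance statistics), uniform cyclic phase shuffling of
every channel × cycle trace (chance levels), five uniform circular draws
(PGP chance), Haar-random subspaces via orthonormalized Gaussian matrices
(principal-angle chance), and phase shuffling of the target region with
refitting of the communication model (Δangles noise). Monte-Carlo p-values
use the add-one convention `p = (1 + #extreme) / (1 + N)`, whose floor at
N = 2000 is 1/2001 ≈ 0.0005. Every mode is deterministic given (seed, N).
Whether the "±" on a chance level denotes the s.d. or the s.e.m. of the
null is ambiguous in common reporting; `stat_result` carries both.

## Decoders

Gait events are detected with a three-class regularized LDA
(foot-strike / foot-off / none; the "none" exemplars sit at the midpoints
between consecutive events). Features are per-channel rates averaged in B
bins over the window [t−L, t]; L ∈ {100,…,500} ms, B ∈ {5, 10} and the
shrinkage coefficient are chosen by cross-validation on the calibration
task (ties to smaller L, then smaller B, then larger regularization), and
the final model is fit on the whole calibration task. At run time the
posterior is evaluated every 10 ms; a detection fires on an upward crossing
of the 0.80 threshold, with a 100 ms same-class refractory period. Because
threshold crossings sit on the rising flank of the posterior, detections
systematically lead the events; the decoder measures this median lead per
class on the calibration task and corrects for it — a standard calibration
step for event-detection decoders. Detections are scored by matching to the
nearest unmatched true event within ±125 ms (configurable; this scoring
window is a package choice), and the F-score averages the two event
classes' harmonic precision–recall means.

Task classification uses the same rLDA with 5-fold cross-validation on
per-cycle behavioral features. EMG envelopes and kinematics are
reconstructed with a linear (Wiener) filter over lagged population rates —
100 ms windows for EMG, 300 ms for kinematics, 10 ms lag spacing — with the
ridge λ cross-validated (5-fold) on the calibration task. The optional
static polynomial cascade stage defaults to degree 1 (purely linear) since
only the linear window parameters matter for the reported analyses;
a degree-3 stage is available. Velocities are first-derivative
Savitzky–Golay estimates (`signal::sgolayfilt`), exact for polynomial
trajectories up to the fitting order.

## The synthetic generator: what it emulates and what it does not

The generator emits, at 1 kHz, `rate = baseline + gain · W z + noise` with
`W` a channel-loading matrix and `z` latent time courses locked to the gait
phase. The study conditions it encodes: 5 tasks, ~100 cycles per task,
cycle durations from a truncated normal (mean 0.94 s, s.d. 0.10 s, bounds
0.3–1.5 s — matching the ~942 ms mean of real peri-gait data), stance
fraction 0.60 ± 0.025 (bounds 0.2–0.8) so that warping is exercised
nontrivially, 48 channels per region by default (64 in the recovery
checks), baseline 20 Hz, gain 5 Hz per latent unit, and white noise of
1 Hz s.d. — a deliberately low-noise regime, since single-trial noise
magnitudes are not constrained by published values and the generator's job
is to make recovery failures attributable to the pipeline, not the noise.

Design choices that make every planted quantity exactly recoverable:

* **Latent curves** are random Fourier series on the circular 100-sample
  phase grid with harmonics up to 9 and unit RMS. The order must satisfy
  `2 · order ≥ n_TI + n_TD` (validated) so the planted latent sets span
  independent directions of the periodic function space; the default of 9
  additionally leaves room for the task-profile construction below while
  staying near the band limit implied by the 50 ms rate smoothing
  (~7 harmonics per ~940 ms cycle).
* **TI latents** are identical across tasks and orthonormal on the grid.
  **TD latents** use a task-profile ⊗ curve construction:
  `g_k(task, phase) = Σ_j u_j[task] ψ_{k,j}(phase)` with J task profiles
  `u_j` orthonormal over tasks and orthogonal to the all-ones vector
  (hence exactly zero across-task mean), and curves `ψ` mutually
  orthonormal and orthogonal to the TI curves. This makes the TD set
  exactly orthogonal with *equal power within every task* — so single-task
  regressions can neither read TD structure out of TI directions nor see a
  badly conditioned TD restriction — while the task-concatenations remain
  exactly orthonormal, keeping the planted variance split additive and
  exact.
* **Channel loadings** have orthonormal columns and, for even latent
  counts, equal per-channel power in the TI and the TD block (cos/sin
  column pairs at distinct spatial frequencies, randomly rotated within
  each block). Equal per-channel power matters: per-channel z-scoring
  reweights channels by their total variance, and with generic random
  loadings this shifts the realized TI share by several points; with flat
  loadings the z-scored data carries the planted split exactly.
* **The communication map** drives the target region through rank-r
  factors with orthonormalized maps and per-factor variance equalization,
  so all r communication dimensions carry comparable power and the 95%
  cumulative rule can recover the planted rank. The alignment parameter α
  weights TI latents by sqrt(α) and TD latents by sqrt(1−α); α = 1 plants
  a purely TI-aligned map, α = 0 a purely TD-aligned one.
* **Behavior** is read out linearly from the latents: six EMG envelopes
  with offsets large enough that rectification never clips (so a linear
  decoder can be exact on noiseless data), and 3 × 4 kinematic channels
  referenced to the across-landmark mean at every sample.

What the generator does **not** emulate: biophysical spiking dynamics
(Poisson emission is available but rates are the default), electrode
nonstationarity, movement artifacts, task-specific cycle-duration
distributions, correlated (shared) noise across channels, and behavioral
events outside the gait cycle. Passing the recovery tests therefore shows
that the pipeline's estimators are correct and well calibrated under the
planted model — not that real cortical data satisfies that model.

## Problem sizes and numerical choices

The test suite runs the recovery checks at 64 channels, 5 tasks × 100
cycles (the full study scale) for the TI-fraction, communication-rank and
Δangles-sign checks, and at 12–32 channels with 15–30 cycles per task
elsewhere; the workflow scripts under `analysis/` use 32 channels and 60
cycles per task. These sizes were chosen so a complete run is comfortable
on a single CPU while keeping all planted-recovery margins wide.

Ties and degeneracies: PGP argmax ties break to the smallest index;
zero-variance channels are flagged and excluded rather than dropped;
rank-deficient `Bbar` columns reduce the communication dimension with a
warning; `k = 0` mode removal is the identity. Seeds are explicit arguments
everywhere randomness enters (channel subsampling, folds, null draws,
generation), and all null modes are reproducible from (seed, N).

## Known limitations

* The dPCA mode count (10 per marginalization) is a budget, not a model
  selection; modes beyond the latent rank capture trial-averaged noise and
  are labeled by whichever part dominates that noise.
* Sequential mode removal is order-dependent across labels; the canonical
  TI-then-TD order is documented and asserted, but removing labels in the
  opposite order yields slightly different residuals.
* The alignment-index normalization ("self") can marginally exceed 1 when
  another task's manifold captures a task's activity better than its own.
* Event-decoder hyperparameter search optimizes classification F at event
  times, which is a proxy for the detection F-score that the run-time
  evaluation reports.
* With odd latent counts the flat channel-loading construction is
  unavailable and the realized TI share can drift a point or two from the
  planted value under z-scoring.
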