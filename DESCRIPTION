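Package: gaitmodes
Title: Task-Dependent and Task-Independent Subspace Analysis of Neural
    Population Activity During Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multi-region neural population
    recordings during repeated gait cycles. Builds peri-gait firing-rate
    tensors by time-warping each gait cycle to a common 100-sample phase
    grid (stance 60 samples, swing 40), estimates manifold dimensionality
    and alignment indices, separates activity into task-independent and
    task-dependent demixed components (dPCA), identifies inter-region
    communication subspaces by ridge plus reduced-rank regression,
    compares subspaces via principal angles, and evaluates gait-event,
    task, and EMG/kinematic decoders. A synthetic session generator
    plants known latent structure (latent subspaces, variance fractions,
    low-rank communication maps) so every statistic has a recoverable
    ground truth; bootstrap, shuffle, and Monte-Carlo permutation nulls
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
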