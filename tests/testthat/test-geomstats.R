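test_that("circular standard deviation follows the angular-deviation convention", {
  expect_equal(circ_sd(rep(0.3, 5)), 0)
  expect_equal(circ_sd(2 * pi * (0:4) / 5), sqrt(2) * 180 / pi,
               tolerance = 1e-9)
  # hand computation: two opposite angles -> Rbar = 0 -> sqrt(2) rad
  expect_equal(circ_sd(c(0, pi), degrees = FALSE), sqrt(2), tolerance = 1e-12)
  # log form diverges as Rbar -> 0 (only floating-point residue bounds it)
  expect_gt(circ_sd(c(0, pi), form = "log", degrees = FALSE), 5)
})

test_that("principal angles match analytic constructions", {
  I4 <- diag(4)
  A <- subspace(I4[, 1:2], "random")
  expect_equal(principal_angles(A, A), c(0, 0), tolerance = 1e-8)
  B <- subspace(I4[, 3:4], "random")
  expect_equal(principal_angles(A, B), c(90, 90), tolerance = 1e-8)

  # two planes in 3-space sharing one line with dihedral angle 30 degrees
  th <- 30 * pi / 180
  P1 <- cbind(c(1, 0, 0), c(0, 1, 0))
  P2 <- cbind(c(1, 0, 0), c(0, cos(th), sin(th)))
  expect_equal(principal_angles(subspace(P1, "random"), subspace(P2, "random")),
               c(0, 30), tolerance = 1e-8)

  # invariance to basis rotation of either argument
  set.seed(1)
  W1 <- gaitmodes:::random_subspace_basis(10, 3)
  W2 <- gaitmodes:::random_subspace_basis(10, 4)
  R1 <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(principal_angles(W1 %*% R1, W2), principal_angles(W1, W2),
               tolerance = 1e-6)
})

test_that("mean principal angle to a random subspace concentrates with dimension", {
  set.seed(2)
  means <- vapply(c(10, 50, 200), function(n) {
    A <- gaitmodes:::random_subspace_basis(n, 3)
    mean(replicate(40, mean(principal_angles(
      A, gaitmodes:::random_subspace_basis(n, 3)))))
  }, numeric(1))
  expect_true(all(diff(means) > 0))  # angles approach 90 deg as n grows
})

test_that("delta angles has the right sign structure and guards its inputs", {
  n <- 15
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(n * n), n)))
  ti5 <- subspace(Q[, 1:5], "task-independent")
  td5 <- subspace(Q[, 6:10], "task-dependent")
  comm_ti <- subspace(Q[, 1:3], "communication")
  comm_td <- subspace(Q[, 6:8], "communication")
  expect_equal(delta_angles(comm_ti, td5, ti5), 90, tolerance = 1e-6)
  expect_equal(delta_angles(comm_td, td5, ti5), -90, tolerance = 1e-6)
  expect_error(delta_angles(comm_ti, subspace(Q[, 6:9], "task-dependent"), ti5),
               "exactly 5")

  # Haar-random communication subspace: mean delta ~ 0 by symmetry
  ds <- replicate(400, delta_angles(
    subspace(gaitmodes:::random_subspace_basis(n, 3), "communication"),
    td5, ti5))
  expect_lt(abs(mean(ds)), 1)
})

test_that("Monte-Carlo p-values follow the add-one convention", {
  null <- 1:2000 / 2000
  expect_equal(mc_pvalue(2, null, "greater"), 1 / 2001)
  expect_equal(mc_pvalue(-1, null, "greater"), 1)
  expect_equal(mc_pvalue(stats::median(null), null, "greater"), 0.5,
               tolerance = 0.01)
  expect_error(mc_pvalue(1, numeric(0)), "empty")
})

test_that("null engine modes are deterministic and behave at fixed points", {
  # bootstrap-split on noiseless identical cycles: null correlation = 1
  curves <- random_curves(3, 2, seed = 4)
  pt <- tensor_from_curves(curves, n_cycles = 5)
  stat_corr <- function(p) perigait_stats(p)$population_cross_task_correlation
  ne <- null_engine(pt, stat_corr, mode = "bootstrap-split", N = 5, seed = 1)
  expect_equal(ne$null, rep(1, 5), tolerance = 1e-9)

  # determinism given (seed, N)
  ne2 <- null_engine(pt, stat_corr, mode = "bootstrap-split", N = 5, seed = 1)
  expect_identical(ne$null, ne2$null)

  # pgp-uniform chance level: mean near 60.33 deg (printed convention)
  ch <- null_engine(NULL, mode = "pgp-uniform", N = 2000, seed = 7)
  expect_equal(ch$null_mean, 60.33, tolerance = 1.5)

  # stat_result serialization carries the provenance fields
  row <- stat_result_row(ch)
  expect_equal(row$N, 2000)
  expect_equal(row$mode, "pgp-uniform")
})

test_that("phase shuffling decorrelates phase-locked activity across tasks", {
  # shared phase-locked structure across tasks plus small task deviations
  base <- random_curves(6, 1, seed = 5)
  curves <- array(0, c(6, 3, 100))
  for (tk in 1:3) curves[, tk, ] <- base[, 1, ] +
      0.2 * random_curves(6, 1, seed = 50 + tk)[, 1, ]
  pt <- tensor_from_curves(curves, n_cycles = 8, noise_sd = 0.05)
  stat_corr <- function(p) perigait_stats(p)$population_cross_task_correlation
  obs <- stat_corr(pt)
  ne <- null_engine(pt, stat_corr, mode = "phase-shuffle", N = 40, seed = 2,
                    observed = obs, direction = "greater")
  expect_lt(abs(ne$null_mean), 0.05)
  expect_equal(ne$p, 1 / 41)  # observed exceeds every shuffled draw
})
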