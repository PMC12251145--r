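test_that("equilibrium loss rates follow each model's constant-size constraints", {
  # model A: pure balance d_i = p_i
  pA <- kinetic_params("A", 0.001, 0.002, 0.003, R_1 = 0.05, R_2 = 0.01)
  expect_equal(unname(equilibrium_loss_rates(pA)), c(0.001, 0.002, 0.003))

  # model D with excessive inter-subset differentiation is infeasible
  pD_bad <- kinetic_params("D", p_N = 1e-3, p_1 = 1e-4, p_2 = 1e-3,
                           R_1 = 0.05, R_2 = 0.01, delta_N = 1e-8,
                           delta_1 = 0.1, k = 2)
  expect_error(equilibrium_loss_rates(pD_bad), class = "tscmkin_infeasible")

  # model B is rejected: its labelled-cell loss rates are free parameters
  pB <- kinetic_params("B", 1e-3, 1e-3, 1e-3, R_1 = 0.05, R_2 = 0.01,
                       dstar_N = 1e-3, dstar_1 = 1e-3, dstar_2 = 1e-3)
  expect_error(equilibrium_loss_rates(pB), "model B")

  # with the derived rates, pool sizes stay constant under the cell-number
  # ODEs over 500 days (ODE oracle), for every equilibrium-constrained model
  for (m in c("A", "C", "D", "E")) {
    pp <- random_feasible_params(m, seed = 300 + match(m, LETTERS))
    sol <- cell_number_oracle(pp, times = c(0, 100, 250, 500))
    drift <- apply(sol[, -1, drop = FALSE], 2, function(x) max(abs(x / x[1] - 1)))
    expect_lt(max(drift), 1e-8)
  }
})

test_that("label trajectories match deSolve integration for random feasible draws", {
  days <- c(1, 5, 14, 30, 49, 70, 100, 140)
  sal <- saliva_model(f = 0.015, delta = 0.06)
  for (m in c("A", "B", "C", "D", "E")) {
    for (r in 1:6) {
      pp <- random_feasible_params(m, seed = 1000 * match(m, LETTERS) + r)
      traj <- label_trajectories(pp, sal, b_w = 5, days)
      mat <- matrix(traj$enrichment, ncol = 3)
      oracle <- label_ode_oracle(pp, sal, 5, days)
      expect_lt(max(abs(mat - oracle)), 1e-6)
      # bounded by the theoretical plateau, non-negative
      expect_true(all(mat >= -1e-12 & mat <= 5 * sal$f + 1e-9))
    }
  }
})

test_that("printed-equation variant of models D/E matches its own ODE oracle and differs from mass balance", {
  days <- c(5, 20, 49, 90, 140)
  sal <- saliva_model(f = 0.015, delta = 0.06)
  for (m in c("D", "E")) {
    pp <- random_feasible_params(m, seed = 77 + match(m, LETTERS))
    printed <- matrix(label_trajectories(pp, sal, 5, days, as_printed = TRUE)$enrichment, ncol = 3)
    oracle <- label_ode_oracle(pp, sal, 5, days, as_printed = TRUE)
    expect_lt(max(abs(printed - oracle)), 1e-6)
    massbal <- matrix(label_trajectories(pp, sal, 5, days)$enrichment, ncol = 3)
    expect_gt(max(abs(printed - massbal)), 0)  # genuinely different bookkeeping
  }
})

test_that("model D collapses to model A when both differentiation flows vanish", {
  sal <- saliva_model(f = 0.015, delta = 0.06)
  days <- c(5, 20, 49, 90, 140)
  pA <- kinetic_params("A", 3e-4, 8e-4, 2e-3, R_1 = 0.05, R_2 = 0.01)
  pD <- kinetic_params("D", 3e-4, 8e-4, 2e-3, R_1 = 0.05, R_2 = 0.01,
                       delta_N = 0, delta_1 = 0, k = 5)
  a <- label_trajectories(pA, sal, 5, days)$enrichment
  d <- label_trajectories(pD, sal, 5, days)$enrichment
  expect_lt(max(abs(a - d)), 1e-10)

  # model B with dstar_i = p_i coincides with model A exactly
  pB <- kinetic_params("B", 3e-4, 8e-4, 2e-3, R_1 = 0.05, R_2 = 0.01,
                       dstar_N = 3e-4, dstar_1 = 8e-4, dstar_2 = 2e-3)
  b <- label_trajectories(pB, sal, 5, days)$enrichment
  expect_lt(max(abs(a - b)), 1e-14)
})

test_that("model A label equals the closed-form convolution of S (quadrature oracle)", {
  sal <- saliva_model(f = 0.02, delta = 0.1)
  pA <- kinetic_params("A", 1e-3, 5e-4, 2e-3, R_1 = 0.05, R_2 = 0.01)
  days <- c(3, 10, 30, 49, 80, 140)
  traj <- matrix(label_trajectories(pA, sal, 5, days)$enrichment, ncol = 3)
  for (j in 1:3) {
    p_j <- c(1e-3, 5e-4, 2e-3)[j]
    conv <- vapply(days, function(tt) {
      stats::integrate(function(u) {
        p_j * 5 * saliva_enrichment(u, sal) * exp(-p_j * (tt - u))
      }, 0, tt, rel.tol = 1e-11, subdivisions = 2000L)$value
    }, numeric(1))
    expect_lt(max(abs(traj[, j] - conv)), 1e-6)
  }
})

test_that("zero saliva forcing gives identically zero label trajectories", {
  # degenerate forcing implemented by a vanishing plateau
  sal0 <- saliva_model(f = 1e-300, delta = 0.1)
  pD <- default_true_params()
  traj <- label_trajectories(pD, sal0, 5, c(5, 50, 140))
  expect_true(all(abs(traj$enrichment) < 1e-290))
})

test_that("fork reparameterization is exact, invertible, and restricted to model C", {
  pC <- kinetic_params("C", p_N = 3e-4, p_1 = 8e-4, p_2 = 2e-3,
                       R_1 = 0.05, R_2 = 0.01, delta_N = 1e-6, k = 9,
                       frac = 0.7, A = 0.03)
  Pi <- fork_reparameterize(pC)
  expect_equal(unname(Pi[["Pi_1"]]),
               8e-4 + 1e-6 * 0.7 * (2^9 - 1) / 0.05)
  back <- fork_invert(Pi[["Pi_1"]], Pi[["Pi_2"]], pC)
  expect_lt(abs(back$p_1 - pC$p_1), 1e-12)
  expect_lt(abs(back$p_2 - pC$p_2), 1e-12)

  # property: random feasible round trips
  for (r in 1:10) {
    pp <- random_feasible_params("C", seed = 4000 + r)
    Pi_r <- fork_reparameterize(pp)
    inv <- fork_invert(Pi_r[["Pi_1"]], Pi_r[["Pi_2"]], pp)
    expect_lt(abs(inv$p_1 - pp$p_1) + abs(inv$p_2 - pp$p_2), 1e-12)
  }

  # delta_N = 0 collapses Pi to p
  p0 <- kinetic_params("C", 3e-4, 8e-4, 2e-3, R_1 = 0.05, R_2 = 0.01,
                       delta_N = 0, k = 9, frac = 0.3)
  expect_equal(unname(fork_reparameterize(p0)), c(8e-4, 2e-3))
  # frac = 1 sends nothing to CD95hi: Pi_2 = p_2
  p1 <- kinetic_params("C", 3e-4, 8e-4, 2e-3, R_1 = 0.05, R_2 = 0.01,
                       delta_N = 1e-6, k = 9, frac = 1)
  expect_equal(unname(fork_reparameterize(p1)[["Pi_2"]]), 2e-3)

  pD <- default_true_params()
  expect_error(fork_reparameterize(pD), "model C")
})

test_that("parameter validation enforces the model-specific field sets", {
  expect_error(kinetic_params("D", 1e-3, 1e-3, 1e-3, R_1 = 0.05, R_2 = 0.01,
                              delta_N = 1e-6, k = 5), "delta_1")
  expect_error(kinetic_params("C", 1e-3, 1e-3, 1e-3, R_1 = 0.05, R_2 = 0.01,
                              delta_N = 1e-6, k = 20, frac = 0.5), "15")
  expect_error(kinetic_params("A", -1e-3, 1e-3, 1e-3, R_1 = 0.05, R_2 = 0.01),
               "non-negative")
  expect_error(kinetic_params("A", 1e-3, 1e-3, 1e-3, R_1 = -1, R_2 = 0.01),
               "positive")
})
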