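test_that("telomere theta: zero cases, A/B age scaling, and sign convention", {
  pA_eq <- kinetic_params("A", 1e-3, 1e-3, 1e-3, R_1 = 0.05, R_2 = 0.01)
  expect_equal(telomere_theta(pA_eq), 0)  # equal proliferation -> no difference

  pD <- default_true_params()
  expect_equal(telomere_theta(pD, telomere_settings(delta_tel = 0)), 0)

  # A/B theta grows linearly with the evaluation age
  pA <- kinetic_params("A", 3e-4, 8e-4, 2e-3, R_1 = 0.05, R_2 = 0.01)
  th34 <- telomere_theta(pA, telomere_settings(age_for_AB_years = 34))
  th68 <- telomere_theta(pA, telomere_settings(age_for_AB_years = 68))
  expect_equal(th68, 2 * th34, tolerance = 1e-12)
  # T_SCM proliferating faster than T_N -> T_SCM shorter -> theta > 0
  expect_gt(th34, 0)

  # models A and B share the independent-pools formula
  pB <- kinetic_params("B", 3e-4, 8e-4, 2e-3, R_1 = 0.05, R_2 = 0.01,
                       dstar_N = 1e-3, dstar_1 = 1e-3, dstar_2 = 1e-3)
  expect_equal(telomere_theta(pB), th34)
})

test_that("equilibrium theta: algebraic steady state equals ODE integration (models C-E)", {
  relax_rates <- function(pp) {
    switch(pp$model,
      C = c(2^pp$k * pp$delta_N * pp$frac / pp$R_1,
            2^pp$k * pp$delta_N * (1 - pp$frac) / pp$R_2),
      D = c(2^pp$k * pp$delta_N / pp$R_1, pp$delta_1 * pp$R_1 / pp$R_2),
      E = c(pp$delta_1 * pp$R_2 / pp$R_1, 2^pp$k * pp$delta_N / pp$R_2))
  }
  for (m in c("C", "D", "E")) {
    done <- 0; r <- 0
    while (done < 4 && r < 60) {
      r <- r + 1
      pp <- random_feasible_params(m, seed = 500 * match(m, LETTERS) + r)
      # only draws whose division-history system relaxes well inside the
      # integration horizon make a meaningful numeric comparison
      if (min(relax_rates(pp)) < 2e-4) next
      done <- done + 1
      alg <- telomere_theta(pp)
      ode <- telomere_theta(pp, telomere_settings(horizon_years = 400, tol = 1e-5),
                            method = "ode")
      expect_lt(abs(alg - ode) / max(abs(alg), 1), 1e-6)
    }
    expect_gte(done, 3)
  }
  # closed-form cross-check of the model-D steady state against the
  # hand-derived expressions
  pp <- random_feasible_params("D", seed = 42)
  nu1 <- pp$k + 2 * (pp$p_1 - pp$p_N) * pp$R_1 / (2^pp$k * pp$delta_N)
  nu2 <- nu1 + 2 * (pp$p_2 - pp$p_N) * pp$R_2 / (pp$delta_1 * pp$R_1)
  w1 <- pp$R_1 / (pp$R_1 + pp$R_2); w2 <- pp$R_2 / (pp$R_1 + pp$R_2)
  expect_lt(abs(telomere_theta(pp) - 50 * (w1 * nu1 + w2 * nu2)), 1e-6)
})

test_that("theta ODE route reports non-convergence for ultra-slow dynamics", {
  slow <- kinetic_params("D", 3e-4, 8e-4, 2e-3, R_1 = 0.05, R_2 = 0.01,
                         delta_N = 1e-9, delta_1 = 1e-9, k = 2)
  expect_error(
    telomere_theta(slow, telomere_settings(horizon_years = 1, tol = 1e-10),
                   method = "ode"),
    "equilibrium")
})

test_that("vaccine-decay observable: initial condition, constancy for A/B, closed forms for C-E", {
  for (m in c("A", "B", "C", "D", "E")) {
    pp <- random_feasible_params(m, seed = 600 + match(m, LETTERS))
    y0 <- yfv_frequency(pp, 0)
    expect_equal(y0$Y, 2 * pp$A)  # total starts at 2A in every model
  }
  # models A/B predict no decline at all
  pA <- kinetic_params("A", 3e-4, 8e-4, 2e-3, R_1 = 0.05, R_2 = 0.01, A = 0.04)
  tt <- c(0, 100, 1000, 10000)
  expect_true(all(yfv_frequency(pA, tt)$Y == 0.08))

  # models D/E: closed forms match numeric integration of the clone ODEs
  for (m in c("D", "E")) {
    pp <- random_feasible_params(m, seed = 700 + match(m, LETTERS))
    d <- equilibrium_loss_rates(pp)
    if (m == "D") {
      rhs <- function(t, y, parms) {
        list(c(-pp$delta_N * 2^pp$k / pp$R_1 * y[1],
               pp$delta_1 * y[1] + (pp$p_2 - d[["d_2"]]) * y[2]))
      }
      idx <- c(T_int = 1, T_hi = 2)
    } else {
      rhs <- function(t, y, parms) {
        list(c(-pp$delta_N * 2^pp$k / pp$R_2 * y[1],
               pp$delta_1 * y[1] + (pp$p_1 - d[["d_1"]]) * y[2]))
      }
      idx <- c(T_hi = 1, T_int = 2)
    }
    tt <- c(0, 50, 200, 1000, 5000)
    num <- deSolve::ode(c(pp$A, pp$A), tt, rhs, NULL, rtol = 1e-12, atol = 1e-14)
    cf <- yfv_frequency(pp, tt)
    expect_lt(max(abs(cf$T_int - num[, 1 + idx[["T_int"]]])), 1e-8)
    expect_lt(max(abs(cf$T_hi - num[, 1 + idx[["T_hi"]]])), 1e-8)
  }

  # fork model: two independent exponentials
  pC <- random_feasible_params("C", seed = 99)
  alpha <- pC$delta_N * pC$frac * 2^pC$k / pC$R_1
  gamma <- pC$delta_N * (1 - pC$frac) * 2^pC$k / pC$R_2
  tt <- c(0, 365, 3652)
  cf <- yfv_frequency(pC, tt)
  expect_equal(cf$T_int, pC$A * exp(-alpha * tt))
  expect_equal(cf$T_hi, pC$A * exp(-gamma * tt))

  # Y non-increasing for the differentiation models
  grid <- seq(0, 36 * 365, length.out = 200)
  for (m in c("C", "D", "E")) {
    pp <- random_feasible_params(m, seed = 800 + match(m, LETTERS))
    expect_true(all(diff(yfv_frequency(pp, grid)$Y) <= 1e-12))
  }
})

test_that("the alpha = gamma coincidence is handled by the analytic limit", {
  # choose delta_1 so that gamma = delta_1 R_1/R_2 equals alpha = delta_N 2^k/R_1
  R_1 <- 0.05; R_2 <- 0.01; delta_N <- 1e-6; k <- 8
  alpha <- delta_N * 2^k / R_1
  delta_1 <- alpha * R_2 / R_1
  pp <- kinetic_params("D", 3e-4, 8e-4, 2e-3, R_1 = R_1, R_2 = R_2,
                       delta_N = delta_N, delta_1 = delta_1, k = k, A = 0.03)
  tt <- c(0, 100, 500, 2000)
  exact <- pp$A * exp(-alpha * tt) + delta_1 * pp$A * tt * exp(-alpha * tt)
  got <- yfv_frequency(pp, tt)$T_hi
  expect_equal(got, exact, tolerance = 1e-10)
  # and a nearby non-degenerate point agrees in the limit
  pp2 <- kinetic_params("D", 3e-4, 8e-4, 2e-3, R_1 = R_1, R_2 = R_2,
                        delta_N = delta_N, delta_1 = delta_1 * (1 + 1e-7),
                        k = k, A = 0.03)
  expect_equal(yfv_frequency(pp2, tt)$T_hi, exact, tolerance = 1e-5)
})

test_that("clonal half-lives match the published closed forms and the net-loss identity", {
  pD <- default_true_params()
  hl <- clonal_half_lives(pD)
  expect_equal(hl$half_life_days[hl$population == "CD95int"],
               pD$R_1 * log(2) / (pD$delta_N * 2^pD$k))
  expect_equal(hl$half_life_days[hl$population == "CD95hi"],
               pD$R_2 * log(2) / (pD$R_1 * pD$delta_1))

  # consistency: ln2 / (d_1 + delta_1 - p_1) with equilibrium d_1
  for (r in 1:8) {
    pp <- random_feasible_params("D", seed = 900 + r)
    d <- equilibrium_loss_rates(pp)
    net <- d[["d_1"]] + pp$delta_1 - pp$p_1
    hh <- clonal_half_lives(pp)
    expect_lt(abs(hh$half_life_days[1] - log(2) / net) / hh$half_life_days[1], 1e-10)
    # clonal persistence >= cellular persistence under self-renewal
    expect_gte(hh$half_life_days[1], log(2) / (d[["d_1"]] + pp$delta_1) - 1e-12)
  }

  # doubling R_1 doubles the CD95int clone half-life, all else equal
  pD2 <- kinetic_params("D", pD$p_N, pD$p_1, pD$p_2, R_1 = 2 * pD$R_1,
                        R_2 = pD$R_2, delta_N = pD$delta_N,
                        delta_1 = pD$delta_1, k = pD$k, A = pD$A)
  expect_equal(clonal_half_lives(pD2)$half_life_days[1],
               2 * hl$half_life_days[1])

  # vanishing inter-subset flow -> infinite CD95hi clone half-life
  pD0 <- kinetic_params("D", pD$p_N, pD$p_1, pD$p_2, R_1 = pD$R_1,
                        R_2 = pD$R_2, delta_N = pD$delta_N, delta_1 = 0,
                        k = pD$k)
  expect_equal(clonal_half_lives(pD0)$half_life_days[2], Inf)

  expect_error(clonal_half_lives(kinetic_params("A", 1e-3, 1e-3, 1e-3,
                                                R_1 = 0.05, R_2 = 0.01)),
               "constant")
})

test_that("residency times are reciprocal total exit rates (with a Monte-Carlo check)", {
  pD <- default_true_params()
  d <- equilibrium_loss_rates(pD)
  rt <- residency_times(pD)
  expect_equal(rt$residency_days[rt$population == "CD95int"],
               1 / (d[["d_1"]] + pD$delta_1))
  expect_equal(rt$residency_days[rt$population == "CD95hi"], 1 / d[["d_2"]])

  # exponential-exit simulation: mean dwell time of 1e5 cells
  exit_rate <- d[["d_1"]] + pD$delta_1
  sim_mean <- withr::with_seed(7, mean(rexp(1e5, rate = exit_rate)))
  expect_lt(abs(sim_mean / rt$residency_days[1] - 1), 0.02)

  expect_error(residency_times(kinetic_params("C", 1e-3, 1e-3, 1e-3,
                                              R_1 = 0.05, R_2 = 0.01,
                                              delta_N = 1e-7, k = 5,
                                              frac = 0.5)),
               "model")
})
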