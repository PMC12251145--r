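# Independent numerical oracles used across the suite. All of them go
# through deSolve (or plain quadrature), never through the package's
# matrix-exponential propagator, so implementation and oracle stay on
# separate routes.

# S(t) by quadrature of the first-order uptake balance w' = delta (u(t) - w),
# with target u = f on [0, t_switch), f/2 on [t_switch, t_end], 0 after.
saliva_ode_oracle <- function(t, f, delta, t_switch = 1, t_end = 49) {
  rhs <- function(tt, w, parms) {
    u <- if (tt < t_switch) f else if (tt <= t_end) f / 2 else 0
    list(delta * (u - w))
  }
  times <- sort(unique(c(0, t_switch, t_end, t)))
  sol <- deSolve::ode(c(w = 0), times, rhs, NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-14)
  sol[match(t, sol[, "time"]), "w"]
}

# blood-monocyte enrichment as the explicit convolution
# L_B(t) = r2 * int_0^t exp(-r2 (t - u)) L_M(u - delay) du, with L_M itself
# integrated numerically from the saliva forcing.
monocyte_convolution_oracle <- function(times, params, saliva) {
  r1 <- params$r1; r2 <- params$r2; bw <- params$b_w; dl <- params$delay
  lm_rhs <- function(tt, y, parms) {
    list(r1 * (bw * tscmkin::saliva_enrichment(max(tt, 0), saliva) - y))
  }
  grid <- seq(0, max(times) + 1, by = 0.05)
  lm <- deSolve::ode(c(L = 0), grid, lm_rhs, NULL, rtol = 1e-11, atol = 1e-13)
  lm_fun <- stats::approxfun(lm[, "time"], lm[, "L"], rule = 2)
  vapply(times, function(tt) {
    if (tt <= dl) return(0)
    # composite Simpson rule on a fine grid (the integrand is smooth within
    # the labelling phases; h = 0.01 d gives ~1e-9 accuracy)
    n <- max(4L, 2L * ceiling((tt - dl) / 0.02))
    u <- seq(dl, tt, length.out = n + 1)
    fu <- r2 * exp(-r2 * (tt - u)) * lm_fun(u - dl)
    h <- (tt - dl) / n
    h / 3 * (fu[1] + fu[n + 1] + 4 * sum(fu[seq(2, n, by = 2)]) +
             2 * sum(fu[seq(3, n - 1, by = 2)]))
  }, numeric(1))
}

# label system integrated by deSolve from the model's ODEs (built from the
# same published equations, but solved numerically rather than propagated)
label_ode_oracle <- function(params, saliva, b_w, times, as_printed = FALSE) {
  sys <- tscmkin:::label_system(params, b_w, as_printed = as_printed)
  rhs <- function(tt, y, parms) {
    list(as.numeric(sys$M %*% y + sys$v * tscmkin::saliva_enrichment(tt, saliva)))
  }
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::ode(c(0, 0, 0), tt, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  sol[match(times, sol[, 1]), 2:4, drop = FALSE]
}

# cell-number system (the population ODEs, with the clonal-burst influx)
cell_number_oracle <- function(params, times) {
  p <- params
  d <- tscmkin::equilibrium_loss_rates(p)
  rhs <- function(tt, y, parms) {
    TN <- y[1]; T1 <- y[2]; T2 <- y[3]
    dyn <- switch(p$model,
      A = c((p$p_N - d[["d_N"]]) * TN,
            (p$p_1 - d[["d_1"]]) * T1,
            (p$p_2 - d[["d_2"]]) * T2),
      C = c((p$p_N - d[["d_N"]] - p$delta_N) * TN,
            (p$p_1 - d[["d_1"]]) * T1 + p$delta_N * p$frac * 2^p$k * TN,
            (p$p_2 - d[["d_2"]]) * T2 + p$delta_N * (1 - p$frac) * 2^p$k * TN),
      D = c((p$p_N - d[["d_N"]] - p$delta_N) * TN,
            p$delta_N * TN * 2^p$k + T1 * p$p_1 - (d[["d_1"]] + p$delta_1) * T1,
            p$delta_1 * T1 + (p$p_2 - d[["d_2"]]) * T2),
      E = c((p$p_N - d[["d_N"]] - p$delta_N) * TN,
            p$delta_1 * T2 + (p$p_1 - d[["d_1"]]) * T1,
            p$delta_N * TN * 2^p$k + (p$p_2 - d[["d_2"]] - p$delta_1) * T2))
    list(dyn)
  }
  y0 <- c(1, p$R_1, p$R_2)   # equilibrium pool sizes relative to T_N
  deSolve::ode(y0, times, rhs, NULL, rtol = 1e-10, atol = 1e-12)
}

# random feasible parameter draws per model, rates on log scale
random_feasible_params <- function(model, seed) {
  withr::with_seed(seed, {
    for (i in 1:200) {
      p_N <- 10^runif(1, -4.5, -2.5)
      p_1 <- 10^runif(1, -4, -2.5)
      p_2 <- 10^runif(1, -3.5, -2)
      delta_N <- 10^runif(1, -7, -5)
      delta_1 <- 10^runif(1, -4, -2.5)
      k <- runif(1, 1, 12)
      frac <- runif(1, 0.05, 0.95)
      R_1 <- 10^runif(1, -2, -0.5)
      R_2 <- 10^runif(1, -2.5, -1)
      pp <- try(switch(model,
        A = kinetic_params("A", p_N, p_1, p_2, R_1, R_2, A = 0.03),
        B = kinetic_params("B", p_N, p_1, p_2, R_1, R_2,
                           dstar_N = 10^runif(1, -4, -2),
                           dstar_1 = 10^runif(1, -4, -2),
                           dstar_2 = 10^runif(1, -4, -2), A = 0.03),
        C = kinetic_params("C", p_N, p_1, p_2, R_1, R_2, delta_N = delta_N,
                           k = k, frac = frac, A = 0.03),
        D = kinetic_params("D", p_N, p_1, p_2, R_1, R_2, delta_N = delta_N,
                           delta_1 = delta_1, k = k, A = 0.03),
        E = kinetic_params("E", p_N, p_1, p_2, R_1, R_2, delta_N = delta_N,
                           delta_1 = delta_1, k = k, A = 0.03)), silent = TRUE)
      if (inherits(pp, "kinetic_params")) {
        ok <- if (model == "B") TRUE else
          !inherits(try(equilibrium_loss_rates(pp), silent = TRUE), "try-error")
        if (ok) return(pp)
      }
    }
    stop("could not draw feasible parameters")
  })
}

# small calibrated bundle + aux shared by inference tests (built once)
make_test_study <- function(seed = 11, truth = default_true_params()) {
  bundle <- calibrate_study(generate_study(truth, seed = seed))
  aux <- aux_data(
    generate_telomere_cohort(truth, seed = seed + 1),
    yfv_totals(generate_yfv_cohort(truth, seed = seed + 2))
  )
  list(bundle = bundle, aux = aux, truth = truth)
}
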