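#' Settings for the telomere-length observable
#'
#' @param delta_tel Base pairs lost per division (default 50).
#' @param age_for_AB_years Donor age (years) at which the age-dependent
#'   theta of the independent models A/B is evaluated (default 34, a median
#'   age for telomere cohorts).
#' @param horizon_years Integration horizon for the numeric (`method =
#'   "ode"`) equilibrium of models C-E (default 100 years).
#' @param tol Equilibrium tolerance on the theta time-derivative
#'   (bp/day, default 1e-8) for the numeric route.
#' @return A list of class `telomere_settings`.
#' @export
telomere_settings <- function(delta_tel = 50, age_for_AB_years = 34,
                              horizon_years = 100, tol = 1e-8) {
  stopifnot(delta_tel >= 0, age_for_AB_years > 0, horizon_years > 0, tol > 0)
  structure(list(delta_tel = delta_tel, age_for_AB_years = age_for_AB_years,
                 horizon_years = horizon_years, tol = tol),
            class = "telomere_settings")
}

#' Predicted telomere-length difference between T_N and T_SCM
#'
#' Telomeres shorten by `delta_tel` base pairs per division, so the
#' difference in mean telomere length between naive T cells and the
#' aggregate T_SCM pool (`theta`, positive when T_SCM is shorter) tracks the
#' pools' cumulative division histories. For the independent models A/B the
#' pools never exchange cells and theta grows linearly with age; it is
#' evaluated at `age_for_AB_years`. For the lineage models C-E the
#' division-history differences relax to a steady state set by the influx of
#' burst-derived cells, and theta is age-independent at equilibrium. The
#' CD95int and CD95hi contributions are weighted by the pool ratios
#' `R_1 : R_2`.
#'
#' @param params A [kinetic_params()] object.
#' @param settings A [telomere_settings()] object.
#' @param method `"algebraic"` (closed-form steady state, default) or
#'   `"ode"` (numeric integration of the division-history system to
#'   equilibrium; errors if the horizon is reached before the theta
#'   derivative falls below `tol`). Ignored for models A/B.
#' @return Predicted theta in base pairs.
#' @export
telomere_theta <- function(params, settings = telomere_settings(),
                           method = c("algebraic", "ode")) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(settings, "telomere_settings"))
  method <- match.arg(method)
  p <- params
  dt <- settings$delta_tel
  if (dt == 0) return(0)
  w1 <- p$R_1 / (p$R_1 + p$R_2)
  w2 <- p$R_2 / (p$R_1 + p$R_2)

  if (p$model %in% c("A", "B")) {
    age_days <- settings$age_for_AB_years * 365.25
    return((w1 * 2 * p$p_1 + w2 * 2 * p$p_2 - 2 * p$p_N) * dt * age_days)
  }

  # nu_i = excess divisions of pool i over T_N; influx of burst-derived
  # cells (which carry k extra divisions) pulls nu towards equilibrium
  rates <- switch(p$model,
    C = list(c1 = 2^p$k * p$delta_N * p$frac / p$R_1,
             c2 = 2^p$k * p$delta_N * (1 - p$frac) / p$R_2,
             chain = FALSE),
    D = list(c1 = 2^p$k * p$delta_N / p$R_1,
             c2 = p$delta_1 * p$R_1 / p$R_2,
             chain = TRUE, first = 1L),
    E = list(c1 = p$delta_1 * p$R_2 / p$R_1,
             c2 = 2^p$k * p$delta_N / p$R_2,
             chain = TRUE, first = 2L)
  )

  if (method == "algebraic") {
    nu <- theta_equilibrium_nu(p, rates)
  } else {
    nu <- theta_ode_nu(p, rates, settings)
  }
  dt * (w1 * nu[1] + w2 * nu[2])
}

theta_equilibrium_nu <- function(p, rates) {
  if (p$model == "C") {
    nu1 <- p$k + 2 * (p$p_1 - p$p_N) / rates$c1
    nu2 <- p$k + 2 * (p$p_2 - p$p_N) / rates$c2
  } else if (p$model == "D") {
    nu1 <- p$k + 2 * (p$p_1 - p$p_N) / rates$c1
    nu2 <- nu1 + 2 * (p$p_2 - p$p_N) / rates$c2
  } else {
    nu2 <- p$k + 2 * (p$p_2 - p$p_N) / rates$c2
    nu1 <- nu2 + 2 * (p$p_1 - p$p_N) / rates$c1
  }
  c(nu1, nu2)
}

theta_ode_nu <- function(p, rates, settings) {
  horizon <- settings$horizon_years * 365.25
  rhs <- function(t, y, parms) {
    if (p$model == "C") {
      d1 <- 2 * (p$p_1 - p$p_N) + rates$c1 * (p$k - y[1])
      d2 <- 2 * (p$p_2 - p$p_N) + rates$c2 * (p$k - y[2])
    } else if (p$model == "D") {
      d1 <- 2 * (p$p_1 - p$p_N) + rates$c1 * (p$k - y[1])
      d2 <- 2 * (p$p_2 - p$p_N) + rates$c2 * (y[1] - y[2])
    } else {
      d2 <- 2 * (p$p_2 - p$p_N) + rates$c2 * (p$k - y[2])
      d1 <- 2 * (p$p_1 - p$p_N) + rates$c1 * (y[2] - y[1])
    }
    list(c(d1, d2))
  }
  sol <- deSolve::ode(c(nu1 = 0, nu2 = 0), times = c(0, horizon / 2, horizon),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  yT <- sol[nrow(sol), c("nu1", "nu2")]
  w1 <- p$R_1 / (p$R_1 + p$R_2); w2 <- p$R_2 / (p$R_1 + p$R_2)
  dth <- rhs(horizon, yT, NULL)[[1]]
  theta_dot <- settings$delta_tel * (w1 * dth[1] + w2 * dth[2])
  if (abs(theta_dot) > settings$tol) {
    rlang::abort(sprintf(
      "division-history system not at equilibrium after %.0f years (|theta_dot| = %.3g bp/day > tol %.3g); increase horizon_years or use method = 'algebraic'",
      settings$horizon_years, abs(theta_dot), settings$tol))
  }
  as.numeric(yT)
}

#' Antigen-specific T_SCM frequency after vaccination
#'
#' Trajectory of a vaccine-induced (e.g. yellow-fever-specific) T_SCM clone
#' population assuming no further influx from the naive pool after
#' vaccination. Each T_SCM pool starts at frequency `A` (% of CD8), so the
#' total starts at `2A`. For the independent models A/B the pools are at
#' equilibrium and the frequency is constant. For the fork model C each
#' pool decays exponentially; for the linear models D/E the first pool
#' decays exponentially and feeds the second (closed two-exponential form,
#' with the analytic limit at the removable `alpha = gamma` singularity).
#'
#' @param params A [kinetic_params()] with `A` set.
#' @param t Days since vaccination (vectorised).
#' @param A_int,A_hi Optional pool-specific initial frequencies overriding
#'   the common `A` (used for subset-resolved predictions).
#' @return A tibble with columns `day`, `T_int`, `T_hi` and `Y = T_int + T_hi`.
#' @export
yfv_frequency <- function(params, t, A_int = NULL, A_hi = NULL) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(t), all(t >= 0))
  p <- params
  A_int <- A_int %||% p$A
  A_hi <- A_hi %||% p$A
  if (is.null(A_int) || is.null(A_hi)) {
    rlang::abort("initial antigen-specific frequency `A` is not set")
  }
  traj <- yfv_pools(p, t, A_int, A_hi)
  tibble::tibble(day = t, T_int = traj$T_int, T_hi = traj$T_hi,
                 Y = traj$T_int + traj$T_hi)
}

yfv_pools <- function(p, t, A_int, A_hi) {
  if (is.null(A_int) || is.null(A_hi)) {
    rlang::abort("initial antigen-specific frequency `A` is not set")
  }
  switch(p$model,
    A = ,
    B = list(T_int = rep(A_int, length(t)), T_hi = rep(A_hi, length(t))),
    C = {
      alpha <- p$delta_N * p$frac * 2^p$k / p$R_1
      gamma <- p$delta_N * (1 - p$frac) * 2^p$k / p$R_2
      list(T_int = A_int * exp(-alpha * t), T_hi = A_hi * exp(-gamma * t))
    },
    D = {
      alpha <- p$delta_N * 2^p$k / p$R_1
      gamma <- p$delta_1 * p$R_1 / p$R_2
      list(T_int = A_int * exp(-alpha * t),
           T_hi = fed_pool(t, A_hi, A_int, p$delta_1, alpha, gamma))
    },
    E = {
      alpha <- p$delta_N * 2^p$k / p$R_2
      gamma <- p$delta_1 * p$R_2 / p$R_1
      list(T_hi = A_hi * exp(-alpha * t),
           T_int = fed_pool(t, A_int, A_hi, p$delta_1, alpha, gamma))
    }
  )
}

# Downstream pool of a linear chain: x' = delta_1 * u(t) - gamma * x with
# u(t) = A_up exp(-alpha t), x(0) = A_self. The alpha = gamma coincidence is
# a removable singularity with limit delta_1 * A_up * t * exp(-alpha t).
fed_pool <- function(t, A_self, A_up, delta_1, alpha, gamma) {
  base <- A_self * exp(-gamma * t)
  scale <- max(alpha, gamma, .Machine$double.eps)
  if (abs(gamma - alpha) <= 1e-9 * scale) {
    base + delta_1 * A_up * t * exp(-alpha * t)
  } else {
    base + delta_1 * A_up * (exp(-alpha * t) - exp(-gamma * t)) / (gamma - alpha)
  }
}

#' Clonal half-lives of the T_SCM subpopulations
#'
#' Half-life of a T-cell *clone* (ln 2 over the pool's net loss rate
#' `d - p`, plus any onward differentiation), the quantity tied to the
#' persistence of immune memory, as opposed to the cellular half-life
#' `ln 2 / d`. Under the equilibrium constraints the net loss reduces to
#' the influx that balances it, giving for model C
#' `R_1 ln2 / (delta_N frac 2^k)` and `R_2 ln2 / (delta_N (1-frac) 2^k)`;
#' for model D `R_1 ln2 / (delta_N 2^k)` and `R_2 ln2 / (R_1 delta_1)`;
#' model E is the mirror image. A zero denominator gives an infinite
#' half-life. Models A/B assume constant antigen-specific pools, so a clone
#' half-life is undefined (error).
#'
#' @param params A [kinetic_params()] for model C, D or E.
#' @return A tibble with columns `population` (`"CD95int"`, `"CD95hi"`) and
#'   `half_life_days`.
#' @export
clonal_half_lives <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  p <- params
  if (p$model %in% c("A", "B")) {
    rlang::abort("models A/B keep antigen-specific pools constant: clone half-life undefined")
  }
  hl <- switch(p$model,
    C = c(p$R_1 * log(2) / (p$delta_N * p$frac * 2^p$k),
          p$R_2 * log(2) / (p$delta_N * (1 - p$frac) * 2^p$k)),
    D = c(p$R_1 * log(2) / (p$delta_N * 2^p$k),
          p$R_2 * log(2) / (p$R_1 * p$delta_1)),
    E = c(p$R_1 * log(2) / (p$R_2 * p$delta_1),
          p$R_2 * log(2) / (p$delta_N * 2^p$k))
  )
  tibble::tibble(population = c("CD95int", "CD95hi"), half_life_days = hl)
}

#' Mean residency times in the T_SCM pools (model D)
#'
#' Average time a cell remains in a pool: the reciprocal of its total
#' per-cell exit rate (disappearance plus onward differentiation), with the
#' disappearance rates taken from the equilibrium constraints. Reported for
#' the winning linear (CD95int-first) lineage model.
#'
#' @param params A model-D [kinetic_params()].
#' @return A tibble with columns `population` and `residency_days`
#'   (`Inf` when a pool has no exit).
#' @export
residency_times <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$model != "D") {
    rlang::abort("residency times are reported for the linear CD95int-first model (D)")
  }
  d <- equilibrium_loss_rates(params)
  exit_int <- d[["d_1"]] + params$delta_1
  exit_hi <- d[["d_2"]]
  tibble::tibble(
    population = c("CD95int", "CD95hi"),
    residency_days = c(if (exit_int > 0) 1 / exit_int else Inf,
                       if (exit_hi > 0) 1 / exit_hi else Inf)
  )
}
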