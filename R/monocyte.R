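#' Monocyte calibration model parameters
#'
#' Mechanistic description of DNA label enrichment in blood monocytes, used
#' to estimate the amplification factor `b_w` that scales body-water
#' enrichment to the M+1 enrichment of newly synthesised DNA. Bone-marrow
#' precursors proliferate at `p_m` and label at `b_w * S(t)`; cells exit the
#' mitotic pool at `r1`, spend a fixed post-mitotic transit time `delay` in
#' the marrow, and blood monocytes disappear at `r2`. Equilibrium of the
#' precursor and blood pools eliminates `p_m` (= `r1`) and ties
#' `r1 = r2 / m_over_b`, leaving `b_w` and `r2` free. Because blood
#' monocytes turn over fast, their enrichment plateaus at `b_w * f`, so the
#' `b_w` estimate is insensitive to `m_over_b` and `delay`.
#'
#' @param b_w Amplification factor (dimensionless, > 0).
#' @param r2 Blood-monocyte disappearance rate (per day, > 0).
#' @param m_over_b Bone-marrow-to-blood monocyte pool ratio (default 2.6).
#' @param delay Post-mitotic transit time in days (default 1.6).
#' @return An object of class `monocyte_params` with derived `r1` and `p_m`.
#' @export
monocyte_params <- function(b_w, r2, m_over_b = 2.6, delay = 1.6) {
  stopifnot(is.numeric(b_w), length(b_w) == 1,
            is.numeric(r2), length(r2) == 1)
  if (!is.finite(b_w) || b_w <= 0) rlang::abort("`b_w` must be positive")
  if (!is.finite(r2) || r2 <= 0) rlang::abort("`r2` must be positive")
  if (m_over_b <= 0 || delay < 0) rlang::abort("invalid m_over_b or delay")
  r1 <- r2 / m_over_b
  structure(list(b_w = b_w, r2 = r2, m_over_b = m_over_b, delay = delay,
                 r1 = r1, p_m = r1),
            class = "monocyte_params")
}

#' @export
print.monocyte_params <- function(x, ...) {
  cat(sprintf(
    "Monocyte calibration: b_w = %.4g, r2 = %.4g /day (M/B = %.3g, delay = %.3g d)\n",
    x$b_w, x$r2, x$m_over_b, x$delay))
  invisible(x)
}

#' Predicted blood-monocyte enrichment trajectory
#'
#' Solves the delayed precursor/blood system exactly: the marrow precursor
#' fraction obeys a linear uptake equation forced by `b_w * S(t)`, and the
#' blood pool is fed by the precursor value `delay` days earlier. The
#' delayed compartment is propagated jointly with the blood compartment on
#' the time-shifted forcing, so no general delay-differential solver is
#' needed.
#'
#' @param times Days since the start of labelling.
#' @param params A [monocyte_params()] object.
#' @param saliva A [saliva_model()].
#' @return A tibble with columns `day` and `enrichment`.
#' @export
monocyte_trajectory <- function(times, params, saliva) {
  if (!inherits(params, "monocyte_params")) rlang::abort("`params` must be monocyte_params")
  if (!inherits(saliva, "saliva_model")) rlang::abort("`saliva` must be a saliva_model")
  # states: (precursor fraction evaluated at t - delay, blood fraction)
  M <- matrix(c(-params$r1, 0,
                params$r2, -params$r2), 2, 2, byrow = TRUE)
  v <- c(params$r1 * params$b_w, 0)
  sol <- piecewise_exp_solve(M, v, saliva, times, shift = params$delay)
  tibble::tibble(day = times, enrichment = sol[, 2])
}

#' Estimate the amplification factor from monocyte enrichment
#'
#' Fits the monocyte model by least squares for `(b_w, r2)` with the pool
#' ratio and transit time held fixed, using the donor's previously
#' calibrated saliva model.
#'
#' @param data Data frame with columns `day`, `enrichment` and optionally
#'   `sd` (analytic SD per point).
#' @param saliva The donor's calibrated [saliva_model()] (or a
#'   `saliva_fit`, from which the model is taken).
#' @param m_over_b,delay Fixed constants (defaults 2.6 and 1.6 days).
#' @param weighted Use `1/sd^2` weights (default `FALSE`).
#' @return A `monocyte_fit` object with `$params` ([monocyte_params()]).
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_monocyte <- function(data, saliva, m_over_b = 2.6, delay = 1.6,
                         weighted = FALSE) {
  if (inherits(saliva, "saliva_fit")) saliva <- saliva$model
  if (!inherits(saliva, "saliva_model")) {
    rlang::abort("monocyte calibration needs the donor's fitted saliva model first")
  }
  data <- check_series(data, c("day", "enrichment"), "monocyte series")
  if (nrow(data) < 3) rlang::abort("monocyte fit needs at least 3 points")
  if (all(data$enrichment == 0)) {
    rlang::abort("monocyte series is identically zero: no plateau information")
  }
  w <- rep(1, nrow(data))
  if (weighted) {
    if (!"sd" %in% names(data) || any(!is.finite(data$sd)) || any(data$sd <= 0)) {
      rlang::abort("weighted fit requires a positive, finite `sd` column")
    }
    w <- 1 / data$sd^2
  }
  rss <- function(logpar) {
    p <- monocyte_params(exp(logpar[1]), exp(logpar[2]), m_over_b, delay)
    pred <- monocyte_trajectory(data$day, p, saliva)$enrichment
    sum(w * (data$enrichment - pred)^2)
  }
  start <- c(log(max(max(data$enrichment) / saliva$f, 0.5)), log(0.2))
  opt <- optim(start, rss, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  # polish from a second start in case the plateau/turnover trade-off
  # stranded the first run
  opt2 <- optim(c(start[1], log(0.05)), rss, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
  if (opt2$value < opt$value) opt <- opt2
  params <- monocyte_params(exp(opt$par[1]), exp(opt$par[2]), m_over_b, delay)
  structure(
    list(params = params, saliva = saliva, data = data,
         rss = opt$value, convergence = opt$convergence, weighted = weighted),
    class = "monocyte_fit"
  )
}

#' @export
print.monocyte_fit <- function(x, ...) {
  cat("Monocyte (amplification factor) calibration fit\n")
  print(x$params)
  cat(sprintf("  RSS = %.3g on %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @rdname fit_monocyte
#' @param x A `monocyte_fit` object.
#' @param ... Unused.
#' @export
tidy.monocyte_fit <- function(x, ...) {
  tibble::tibble(term = c("b_w", "r2"),
                 estimate = c(x$params$b_w, x$params$r2))
}

#' @rdname fit_monocyte
#' @export
glance.monocyte_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, nobs = nrow(x$data),
                 converged = x$convergence == 0)
}

#' @rdname fit_monocyte
#' @param object A `monocyte_fit` object.
#' @export
autoplot.monocyte_fit <- function(object, ...) {
  grid_t <- seq(0, max(object$data$day), length.out = 200)
  grid <- monocyte_trajectory(grid_t, object$params, object$saliva)
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$day, y = .data$enrichment)) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Days since start of labelling",
                  y = "Monocyte DNA M+1 enrichment",
                  title = "Monocyte calibration") +
    ggplot2::theme_minimal()
  if ("sd" %in% names(object$data)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$enrichment - .data$sd,
                   ymax = .data$enrichment + .data$sd), width = 0)
  }
  p
}
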