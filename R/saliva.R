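#' Body-water label availability model
#'
#' Empirical description of deuterium availability in body water over a
#' three-part heavy-water drinking protocol: a full-dose loading day, a
#' half-dose maintenance phase, and washout after intake stops. During each
#' uptake phase the body-water enrichment relaxes at the water turnover rate
#' `delta` towards the phase's target (the plateau `f`, then `f/2`), and
#' decays exponentially after the end of labelling. The resulting
#' availability curve \eqn{S(t)} is continuous, starts at zero and returns
#' to zero.
#'
#' @param f Plateau enrichment fraction during the full-dose phase
#'   (dimensionless, in (0, 1)).
#' @param delta Body-water turnover rate (per day, > 0).
#' @param t_switch Day the full dose ends and the half dose begins
#'   (default 1).
#' @param t_end Day label intake stops (default 49).
#' @return An object of class `saliva_model`.
#' @seealso [saliva_enrichment()], [fit_saliva()]
#' @export
#' @examples
#' m <- saliva_model(f = 0.02, delta = 0.1)
#' saliva_enrichment(c(0, 1, 49, 100), m)
saliva_model <- function(f, delta, t_switch = 1, t_end = 49) {
  stopifnot(is.numeric(f), length(f) == 1, is.finite(f),
            is.numeric(delta), length(delta) == 1, is.finite(delta))
  if (f <= 0 || f >= 1) rlang::abort("`f` must lie in (0, 1).")
  if (delta <= 0) rlang::abort("`delta` must be positive.")
  if (!(t_switch > 0 && t_end > t_switch)) {
    rlang::abort("need 0 < t_switch < t_end")
  }
  structure(list(f = f, delta = delta, t_switch = t_switch, t_end = t_end),
            class = "saliva_model")
}

#' @export
print.saliva_model <- function(x, ...) {
  cat(sprintf(
    "Body-water label availability: f = %.4g, delta = %.4g /day (dose switch day %g, end of labelling day %g)\n",
    x$f, x$delta, x$t_switch, x$t_end))
  invisible(x)
}

# Piecewise-exponential segments of S(t): on each segment starting at `start`,
# S(t) = a + b * exp(-delta * (t - start)). Shared with the linear-system
# propagator used for all label trajectories.
saliva_phases <- function(model) {
  f <- model$f; delta <- model$delta
  t1 <- model$t_switch; t2 <- model$t_end
  s1 <- f * (1 - exp(-delta * t1))
  s2 <- f / 2 + (s1 - f / 2) * exp(-delta * (t2 - t1))
  list(
    start = c(0, t1, t2),
    a = c(f, f / 2, 0),
    b = c(-f, s1 - f / 2, s2),
    delta = delta
  )
}

#' Evaluate body-water label availability S(t)
#'
#' @param t Days since the start of labelling (non-negative, vectorised).
#' @param model A [saliva_model()].
#' @return Enrichment fraction at each `t`.
#' @export
saliva_enrichment <- function(t, model) {
  if (!inherits(model, "saliva_model")) {
    rlang::abort("`model` must be a saliva_model")
  }
  stopifnot(is.numeric(t))
  if (any(t < 0)) rlang::abort("negative times are not defined: label intake starts at t = 0")
  ph <- saliva_phases(model)
  idx <- findInterval(t, ph$start)
  ph$a[idx] + ph$b[idx] * exp(-ph$delta * (t - ph$start[idx]))
}

#' Fit the body-water availability model to saliva enrichment measurements
#'
#' Least-squares estimation of the plateau fraction `f` and the body-water
#' turnover rate `delta` from a saliva time series. When per-point analytic
#' standard deviations are available, `weighted = TRUE` uses inverse-variance
#' weights; the default is ordinary (unweighted) least squares.
#'
#' @param data A data frame with columns `day` and `enrichment` (optionally
#'   `sd`). Needs at least 3 points spanning the labelling and washout
#'   phases.
#' @param t_switch,t_end Protocol day of the dose switch and the end of
#'   labelling (defaults 1 and 49 days).
#' @param weighted Use `1/sd^2` weights if a finite positive `sd` column is
#'   present (default `FALSE`).
#' @param start Optional named list of starting values for `f` and `delta`.
#' @return A `saliva_fit` object; `$model` is the fitted [saliva_model()].
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_saliva <- function(data, t_switch = 1, t_end = 49, weighted = FALSE,
                       start = NULL) {
  data <- check_series(data, c("day", "enrichment"))
  if (nrow(data) < 3) {
    rlang::abort("saliva fit needs at least 3 time points spanning labelling and washout")
  }
  if (all(data$enrichment == 0)) {
    rlang::abort("saliva series is identically zero: no label information to fit")
  }
  start <- start %||% list(f = max(data$enrichment), delta = 0.05)
  w <- rep(1, nrow(data))
  if (weighted) {
    if (!"sd" %in% names(data) || any(!is.finite(data$sd)) || any(data$sd <= 0)) {
      rlang::abort("weighted fit requires a positive, finite `sd` column")
    }
    w <- 1 / data$sd^2
  }
  fit <- minpack.lm::nlsLM(
    enrichment ~ saliva_enrichment(day, saliva_model(f, delta, t_switch, t_end)),
    data = data,
    start = start,
    weights = w,
    lower = c(f = 1e-8, delta = 1e-6),
    upper = c(f = 0.5, delta = 10),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
  )
  est <- coef(fit)
  structure(
    list(
      model = saliva_model(est[["f"]], est[["delta"]], t_switch, t_end),
      nls = fit,
      data = data,
      weighted = weighted
    ),
    class = "saliva_fit"
  )
}

#' @export
print.saliva_fit <- function(x, ...) {
  cat("Saliva (body-water) calibration fit\n")
  print(x$model)
  cat(sprintf("  RSS = %.3g on %d points\n", sum(resid(x$nls)^2), nrow(x$data)))
  invisible(x)
}

#' @rdname fit_saliva
#' @param x A `saliva_fit` object.
#' @param ... Unused.
#' @export
tidy.saliva_fit <- function(x, ...) {
  s <- summary(x$nls)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"]
  )
}

#' @rdname fit_saliva
#' @export
glance.saliva_fit <- function(x, ...) {
  tibble::tibble(
    rss = sum(resid(x$nls)^2),
    sigma = summary(x$nls)$sigma,
    nobs = nrow(x$data),
    converged = x$nls$convInfo$isConv
  )
}

#' @rdname fit_saliva
#' @param object A `saliva_fit` object.
#' @export
autoplot.saliva_fit <- function(object, ...) {
  grid <- tibble::tibble(day = seq(0, max(object$data$day), length.out = 400))
  grid$enrichment <- saliva_enrichment(grid$day, object$model)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$day, y = .data$enrichment)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Days since start of labelling",
                  y = "Body-water enrichment (fraction)",
                  title = "Saliva deuterium availability") +
    ggplot2::theme_minimal()
}

# shared column validation for tidy time-series inputs
check_series <- function(data, cols, what = "series") {
  if (!is.data.frame(data)) rlang::abort(sprintf("%s must be a data frame", what))
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    rlang::abort(sprintf("%s is missing column(s): %s", what,
                         paste(missing, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  if (any(!is.finite(data[[cols[1]]])) ) {
    rlang::abort(sprintf("%s has non-finite values in `%s`", what, cols[1]))
  }
  if (any(data[[cols[1]]] < 0)) {
    rlang::abort(sprintf("%s has negative times in `%s`", what, cols[1]))
  }
  dplyr::arrange(data, .data[[cols[1]]])
}
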