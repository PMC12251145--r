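# Free-parameter layout per model and data mode. Each parameter carries a
# box (lower, upper) and a scale: "log" parameters are searched on log10
# scale (rates span orders of magnitude), "linear" ones (k, frac) on their
# natural scale. Both are mapped to the real line by a logistic transform
# so the local polisher is unconstrained.
param_spec <- function(model, data_mode = c("all", "label_only"),
                       bounds = NULL) {
  data_mode <- match.arg(data_mode)
  rate <- list(lower = 1e-10, upper = 0.5, scale = "log")
  spec <- switch(model,
    A = list(p_N = rate, p_1 = rate, p_2 = rate),
    B = list(p_N = rate, p_1 = rate, p_2 = rate,
             dstar_N = rate, dstar_1 = rate, dstar_2 = rate),
    C = if (data_mode == "label_only") {
      list(p_N = rate, Pi_1 = rate, Pi_2 = rate, delta_N = rate,
           frac = list(lower = 0, upper = 1, scale = "linear"))
    } else {
      list(p_N = rate, p_1 = rate, p_2 = rate, delta_N = rate,
           k = list(lower = 0, upper = 15, scale = "linear"),
           frac = list(lower = 0, upper = 1, scale = "linear"))
    },
    D = ,
    E = list(p_N = rate, p_1 = rate, p_2 = rate, delta_N = rate,
             delta_1 = rate,
             k = list(lower = 0, upper = 15, scale = "linear"))
  )
  if (data_mode == "all") {
    spec$A <- list(lower = 1e-4, upper = 1, scale = "log")
  }
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      if (!nm %in% names(spec)) next
      spec[[nm]]$lower <- bounds[[nm]][1]
      spec[[nm]]$upper <- bounds[[nm]][2]
    }
  }
  spec
}

# local polish: quasi-Newton descent (nlminb) followed by a short
# Nelder-Mead cleanup, both on the unconstrained transformed scale
polish_z <- function(z0, obj_z, maxit) {
  o1 <- tryCatch(
    stats::nlminb(z0, obj_z,
                  control = list(iter.max = maxit, eval.max = 3 * maxit)),
    error = function(e) NULL)
  z1 <- if (!is.null(o1) && all(is.finite(o1$par))) o1$par else z0
  optim(z1, obj_z, method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = 1e-12))
}

# unconstrained z <-> natural parameter vectors
spec_from_z <- function(z, spec) {
  vapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    u <- plogis(z[i])
    if (s$scale == "log") {
      10^(log10(s$lower) + u * (log10(s$upper) - log10(s$lower)))
    } else {
      s$lower + u * (s$upper - s$lower)
    }
  }, numeric(1)) |> setNames(names(spec))
}

spec_to_z <- function(x, spec) {
  vapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    u <- if (s$scale == "log") {
      (log10(x[i]) - log10(s$lower)) / (log10(s$upper) - log10(s$lower))
    } else {
      (x[i] - s$lower) / (s$upper - s$lower)
    }
    qlogis(min(max(u, 1e-8), 1 - 1e-8))
  }, numeric(1)) |> setNames(names(spec))
}

# Build a kinetic_params (or a Pi-parameterized label system) from a named
# natural-parameter vector.
materialize_params <- function(x, model, bundle, data_mode) {
  if (model == "C" && data_mode == "label_only") {
    return(list(pi_mode = TRUE, x = x))
  }
  g <- function(nm) if (nm %in% names(x)) x[[nm]] else NULL
  kinetic_params(model,
    p_N = g("p_N"), p_1 = g("p_1"), p_2 = g("p_2"),
    R_1 = bundle$R_1, R_2 = bundle$R_2,
    delta_N = g("delta_N"), delta_1 = g("delta_1"),
    k = g("k"), frac = g("frac"),
    dstar_N = g("dstar_N"), dstar_1 = g("dstar_1"), dstar_2 = g("dstar_2"),
    A = g("A"))
}

#' Fit a lineage model to one donor's study
#'
#' Steps 3+ of the fitting procedure: with the saliva and monocyte
#' calibrations fixed, minimize the joint mean-normalized sum of squares
#' over the model's free kinetic parameters by multi-start random search -
#' `n_starts` starting points drawn inside the (log-scaled) parameter box
#' from a seeded stream - each followed by a Nelder-Mead polish. The best
#' polished start wins; given `master_seed` the result is deterministic,
#' and the first `n` starts of a longer run coincide with a shorter run's
#' (so increasing `n_starts` can only improve the objective).
#'
#' When `data_mode = "label_only"` and `model = "C"` the fork model is
#' fitted in its identifiable label-only parameterization
#' (`p_N, Pi_1, Pi_2, frac, delta_N`; see [fork_reparameterize()]).
#'
#' @param bundle A calibrated [study_bundle()].
#' @param aux An [aux_data()] object (ignored, and may be `NULL`, when
#'   `data_mode = "label_only"`).
#' @param model Lineage model id, one of `"A"`..`"E"`.
#' @param n_starts Number of random restarts (default 30).
#' @param bounds Optional named list of `c(lower, upper)` overrides.
#' @param master_seed Integer seed controlling every random draw.
#' @param data_mode `"all"` (labelling + telomere + vaccine) or
#'   `"label_only"`.
#' @param config An [objective_config()].
#' @param maxit Maximum Nelder-Mead iterations per start (default 500).
#' @return A `tscm_fit` object with elements `params` (best-fit
#'   [kinetic_params()]), `objective`, `par` (named vector), `starts`
#'   (objective per restart) and bookkeeping. Supports [tidy()],
#'   [glance()], [autoplot()].
#' @export
fit_kinetic_model <- function(bundle, aux, model = "D", n_starts = 30,
                              bounds = NULL, master_seed = 1,
                              data_mode = c("all", "label_only"),
                              config = objective_config(), maxit = 500) {
  stopifnot(inherits(bundle, "study_bundle"))
  data_mode <- match.arg(data_mode)
  model <- match.arg(model, c("A", "B", "C", "D", "E"))
  if (is.null(bundle$b_w)) rlang::abort("bundle must be calibrated first (calibrate_study())")
  if (data_mode == "all" && is.null(aux)) {
    rlang::abort("joint fitting needs aux_data (telomere + vaccine cohorts); use data_mode = 'label_only' otherwise")
  }
  if (data_mode == "label_only") aux <- NULL
  spec <- param_spec(model, data_mode, bounds)
  npar <- length(spec)

  obj_fun <- objective_closure(bundle, aux, config)
  obj_z <- function(z) {
    if (any(!is.finite(z))) return(Inf)
    x <- spec_from_z(z, spec)
    val <- tryCatch({
      if (model == "C" && data_mode == "label_only") {
        sys <- label_system_fork_pi(x[["p_N"]], x[["Pi_1"]], x[["Pi_2"]],
                                    x[["frac"]], x[["delta_N"]],
                                    bundle$R_1, bundle$R_2, bundle$b_w)
        obj_fun(NULL, sys = sys)
      } else {
        obj_fun(materialize_params(x, model, bundle, data_mode))
      }
    }, tscmkin_infeasible = function(e) Inf)
    if (!is.finite(val)) Inf else val
  }

  # feasible starting points by rejection from one seeded stream, so the
  # first n starts of a longer run coincide with a shorter run's
  starts <- withr::with_seed(master_seed, {
    lapply(seq_len(n_starts), function(i) {
      for (try in 1:500) {
        z <- qlogis(runif(npar, 0.02, 0.98))
        if (is.finite(obj_z(z))) return(z)
      }
      NULL
    })
  })
  starts <- starts[!vapply(starts, is.null, logical(1))]
  if (!length(starts)) {
    rlang::abort("all restarts were infeasible: every sampled parameter point violated the equilibrium constraints")
  }

  best <- NULL
  start_objs <- numeric(length(starts))
  for (i in seq_along(starts)) {
    opt <- polish_z(starts[[i]], obj_z, maxit)
    start_objs[i] <- opt$value
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || !is.finite(best$value)) {
    rlang::abort("all restarts were infeasible: every sampled parameter point violated the equilibrium constraints")
  }
  x_best <- spec_from_z(best$par, spec)
  params <- if (model == "C" && data_mode == "label_only") {
    template <- kinetic_params("C", p_N = x_best[["p_N"]], p_1 = 0, p_2 = 0,
                               R_1 = bundle$R_1, R_2 = bundle$R_2,
                               delta_N = x_best[["delta_N"]], k = 1,
                               frac = x_best[["frac"]])
    structure(list(pi = x_best, template = template), class = "fork_pi_fit")
  } else {
    materialize_params(x_best, model, bundle, data_mode)
  }

  blocks <- if (inherits(params, "kinetic_params")) {
    tryCatch(residual_blocks(params, bundle, aux, config),
             tscmkin_infeasible = function(e) NULL)
  } else NULL

  structure(list(
    model = model, params = params, par = x_best, objective = best$value,
    starts = start_objs, spec = spec, data_mode = data_mode,
    donor_id = bundle$donor_id, b_w = bundle$b_w,
    bundle = bundle, aux = aux, config = config,
    master_seed = master_seed, n_starts = n_starts, maxit = maxit,
    convergence = best$convergence,
    blocks = blocks
  ), class = "tscm_fit")
}

#' @export
print.tscm_fit <- function(x, ...) {
  cat(sprintf("Lineage model %s fit, donor %s (%s data)\n",
              x$model, x$donor_id,
              if (x$data_mode == "all") "labelling + telomere + vaccine" else "labelling only"))
  cat(sprintf("  objective = %.6g over %d restarts (seed %d)\n",
              x$objective, x$n_starts, x$master_seed))
  cat("  estimates:\n")
  est <- x$par
  cat(paste0("    ", names(est), " = ", signif(est, 3), collapse = "\n"), "\n")
  invisible(x)
}

#' @rdname fit_kinetic_model
#' @param x,object A `tscm_fit` object.
#' @param ... Unused.
#' @export
tidy.tscm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname fit_kinetic_model
#' @export
glance.tscm_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, donor_id = x$donor_id, objective = x$objective,
    n_starts = x$n_starts, data_mode = x$data_mode,
    converged = x$convergence == 0, master_seed = x$master_seed
  )
}

#' @rdname fit_kinetic_model
#' @export
autoplot.tscm_fit <- function(object, ...) {
  b <- object$bundle
  days <- seq(0, max(b$labels$day), length.out = 300)
  if (inherits(object$params, "kinetic_params")) {
    pred <- label_trajectories(object$params, b$saliva_fit$model, b$b_w, days,
                               as_printed = object$config$as_printed)
  } else {
    pi <- object$params$pi
    sys <- label_system_fork_pi(pi[["p_N"]], pi[["Pi_1"]], pi[["Pi_2"]],
                                pi[["frac"]], pi[["delta_N"]],
                                b$R_1, b$R_2, b$b_w)
    sol <- piecewise_exp_solve(sys$M, sys$v, b$saliva_fit$model, days)
    pred <- tibble::tibble(day = rep(days, 3),
                           population = rep(c("T_N", "CD95int", "CD95hi"),
                                            each = length(days)),
                           enrichment = c(sol))
  }
  ggplot2::ggplot(b$labels, ggplot2::aes(x = .data$day, y = .data$enrichment)) +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~population, scales = "free_y") +
    ggplot2::labs(x = "Days since start of labelling",
                  y = "DNA M+1 enrichment",
                  title = sprintf("Model %s fit, donor %s", object$model, object$donor_id)) +
    ggplot2::theme_minimal()
}
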