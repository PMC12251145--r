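#' Predict subset-resolved decay of vaccine-specific T_SCM
#'
#' Out-of-sample prediction of the antigen-specific CD95int and CD95hi
#' frequencies over a multi-decade horizon, using a fitted lineage model's
#' kinetic parameters but with the initial condition of each subset taken
#' from data: the median frequency of that subset among cohort donors
#' sampled within one year of vaccination.
#'
#' @param fit A `tscm_fit` for model C, D or E.
#' @param cohort Subset-resolved cohort tibble with columns `years`,
#'   `subset` (`"CD95int"` / `"CD95hi"`) and `freq_cd8` (% of CD8), e.g.
#'   from [generate_yfv_cohort()].
#' @param horizon_years Prediction horizon (default 35 years).
#' @param boot Optional `tscm_boot`; when given, each bootstrap replicate's
#'   parameters produce a prediction band.
#' @param n_grid Number of time points on the prediction grid.
#' @return A `tscm_prediction` object: `$trajectories` tibble (`years`,
#'   `subset`, `frequency`) and optionally `$band` with per-replicate
#'   trajectories. Supports [autoplot()].
#' @export
predict_subset_decay <- function(fit, cohort, horizon_years = 35,
                                 boot = NULL, n_grid = 200) {
  stopifnot(inherits(fit, "tscm_fit"))
  if (!inherits(fit$params, "kinetic_params") ||
      !fit$params$model %in% c("C", "D", "E")) {
    rlang::abort("subset-decay prediction needs a fitted differentiation model (C, D or E)")
  }
  cohort <- tibble::as_tibble(cohort)
  need <- setdiff(c("years", "subset", "freq_cd8"), names(cohort))
  if (length(need)) {
    rlang::abort(paste0("cohort is missing column(s): ", paste(need, collapse = ", ")))
  }
  early <- cohort[cohort$years <= 1, , drop = FALSE]
  inits <- tapply(early$freq_cd8, early$subset, median)
  if (any(is.na(inits[c("CD95int", "CD95hi")]))) {
    rlang::abort("no cohort donors sampled within 1 year of vaccination for one of the subsets; cannot set initial conditions")
  }
  A_int <- inits[["CD95int"]]; A_hi <- inits[["CD95hi"]]

  grid_years <- seq(0, horizon_years, length.out = n_grid)
  traj_of <- function(params) {
    tr <- yfv_frequency(params, grid_years * DAYS_PER_YEAR,
                        A_int = A_int, A_hi = A_hi)
    tibble::tibble(
      years = rep(grid_years, 2),
      subset = rep(c("CD95int", "CD95hi"), each = length(grid_years)),
      frequency = c(tr$T_int, tr$T_hi)
    )
  }
  out <- list(trajectories = traj_of(fit$params),
              initials = c(CD95int = A_int, CD95hi = A_hi),
              model = fit$params$model, donor_id = fit$donor_id,
              cohort = cohort)
  if (!is.null(boot)) {
    stopifnot(inherits(boot, "tscm_boot"))
    out$band <- purrr::imap_dfr(
      split(boot$replicates, seq_len(nrow(boot$replicates))),
      function(row, i) {
        x <- as.list(row)
        params <- tryCatch(
          materialize_params(unlist(x[names(fit$spec)]), fit$model,
                             fit$bundle, fit$data_mode),
          error = function(e) NULL)
        if (is.null(params)) return(NULL)
        tr <- traj_of(params)
        tr$replicate <- as.integer(i)
        tr
      })
  }
  structure(out, class = "tscm_prediction")
}

#' @export
print.tscm_prediction <- function(x, ...) {
  cat(sprintf("Subset-resolved decay prediction (model %s, donor %s)\n",
              x$model, x$donor_id))
  cat(sprintf("  initial medians (within 1 yr): CD95int %.4g, CD95hi %.4g %% of CD8\n",
              x$initials[["CD95int"]], x$initials[["CD95hi"]]))
  invisible(x)
}

#' @rdname predict_subset_decay
#' @param object A `tscm_prediction` object.
#' @param ... Unused.
#' @export
autoplot.tscm_prediction <- function(object, ...) {
  p <- ggplot2::ggplot(object$trajectories,
                       ggplot2::aes(x = .data$years, y = .data$frequency))
  if (!is.null(object$band)) {
    p <- p + ggplot2::geom_line(
      data = object$band,
      ggplot2::aes(group = .data$replicate), colour = "grey80", linewidth = 0.2)
  }
  p +
    ggplot2::geom_point(data = object$cohort,
                        ggplot2::aes(y = .data$freq_cd8), size = 1) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~subset, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Years since vaccination",
                  y = "Antigen-specific frequency (% of CD8)") +
    ggplot2::theme_minimal()
}
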