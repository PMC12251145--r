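#' Configuration of the joint objective
#'
#' @param normalization `"pooled"` (default): label residuals from all
#'   three T-cell pools are normalized by the mean of all label
#'   observations, i.e. labelling counts as one data type; `"per_pool"`
#'   normalizes each pool by its own mean.
#' @param include_multiple_vaccinees Keep recipients of repeated
#'   vaccinations in the vaccine-decay block (default `FALSE`).
#' @param as_printed Use the published (non-mass-balance) label inflow for
#'   models D/E (default `FALSE`).
#' @param theta_settings A [telomere_settings()] object (bp per division, A/B evaluation age).
#' @return A list of class `objective_config`.
#' @export
objective_config <- function(normalization = c("pooled", "per_pool"),
                             include_multiple_vaccinees = FALSE,
                             as_printed = FALSE,
                             theta_settings = telomere_settings()) {
  structure(list(
    normalization = match.arg(normalization),
    include_multiple_vaccinees = include_multiple_vaccinees,
    as_printed = as_printed,
    theta_settings = theta_settings
  ), class = "objective_config")
}

DAYS_PER_YEAR <- 365.25

# Per-data-type blocks of mean-normalized residuals. Residuals are
# (observation - prediction) / mean(observations of that data type), so the
# three heterogeneous data sets contribute on a common scale.
residual_blocks <- function(params, bundle, aux = NULL,
                            config = objective_config(),
                            label_system_override = NULL) {
  b_w <- bundle$b_w %||% rlang::abort("bundle must be calibrated (run calibrate_study())")
  saliva <- bundle$saliva_fit$model
  lab <- bundle$labels

  if (is.null(label_system_override)) {
    sys <- label_system(params, b_w, as_printed = config$as_printed)
  } else {
    sys <- label_system_override
  }
  days <- sort(unique(lab$day))
  sol <- piecewise_exp_solve(sys$M, sys$v, saliva, days)
  colnames(sol) <- c("T_N", "CD95int", "CD95hi")
  pred <- sol[match(lab$day, days) + (match(lab$population, colnames(sol)) - 1) * length(days)]

  if (config$normalization == "pooled") {
    lab_scale <- rep(mean(lab$enrichment), nrow(lab))
  } else {
    pool_means <- tapply(lab$enrichment, lab$population, mean)
    lab_scale <- as.numeric(pool_means[lab$population])
  }
  blocks <- list(tibble::tibble(
    data_type = "label",
    residual = (lab$enrichment - pred) / lab_scale
  ))

  if (!is.null(aux)) {
    th_pred <- telomere_theta(params, config$theta_settings)
    th <- aux$telomere
    blocks <- c(blocks, list(tibble::tibble(
      data_type = "telomere",
      residual = (th$theta_bp - th_pred) / mean(th$theta_bp)
    )))

    yf <- aux$yfv
    if (!config$include_multiple_vaccinees) {
      yf <- yf[!yf$multiple_vaccination, , drop = FALSE]
    }
    y_pred <- yfv_frequency(params, yf$years * DAYS_PER_YEAR)$Y
    blocks <- c(blocks, list(tibble::tibble(
      data_type = "yfv",
      residual = (yf$freq_cd8 - y_pred) / mean(yf$freq_cd8)
    )))
  }
  dplyr::bind_rows(blocks)
}

# Fast path for optimizers: precompute the data-dependent pieces once and
# return a closure evaluating the sum of squared normalized residuals for a
# kinetic_params (or a raw label system when `sys_only` calls pass one).
objective_closure <- function(bundle, aux, config) {
  b_w <- bundle$b_w %||% rlang::abort("bundle must be calibrated (run calibrate_study())")
  saliva <- bundle$saliva_fit$model
  lab <- bundle$labels
  days <- sort(unique(lab$day))
  pops <- c("T_N", "CD95int", "CD95hi")
  idx <- match(lab$day, days) + (match(lab$population, pops) - 1) * length(days)
  obs <- lab$enrichment
  if (config$normalization == "pooled") {
    lab_scale <- rep(mean(obs), length(obs))
  } else {
    pool_means <- tapply(obs, lab$population, mean)
    lab_scale <- as.numeric(pool_means[lab$population])
  }
  th_obs <- NULL
  if (!is.null(aux)) {
    th_obs <- aux$telomere$theta_bp
    th_mean <- mean(th_obs)
    yf <- aux$yfv
    if (!config$include_multiple_vaccinees) yf <- yf[!yf$multiple_vaccination, , drop = FALSE]
    yf_days <- yf$years * DAYS_PER_YEAR
    yf_obs <- yf$freq_cd8
    yf_mean <- mean(yf_obs)
  }
  function(params, sys = NULL) {
    if (is.null(sys)) sys <- label_system(params, b_w, as_printed = config$as_printed)
    sol <- piecewise_exp_solve(sys$M, sys$v, saliva, days)
    ss <- sum(((obs - sol[idx]) / lab_scale)^2)
    if (!is.null(th_obs)) {
      th_pred <- telomere_theta(params, config$theta_settings)
      ss <- ss + sum(((th_obs - th_pred) / th_mean)^2)
      yv <- yfv_pools(params, yf_days, params$A, params$A)
      ss <- ss + sum(((yf_obs - (yv$T_int + yv$T_hi)) / yf_mean)^2)
    }
    ss
  }
}

#' Joint sum-of-squares objective over labelling, telomere and vaccine data
#'
#' The fitting criterion: for each data type the residuals (observation
#' minus model prediction) are normalized by the mean of that data type's
#' observations, and the objective is the sum of all squared normalized
#' residuals. Supplying `aux = NULL` gives the label-only objective.
#' Parameter points whose equilibrium disappearance rates are negative
#' return `Inf` so optimizers reject them.
#'
#' @param params A [kinetic_params()] object.
#' @param bundle A calibrated [study_bundle()].
#' @param aux An [aux_data()] object, or `NULL` for label-only fitting.
#' @param config An [objective_config()].
#' @return The scalar objective (>= 0, possibly `Inf`).
#' @export
joint_objective <- function(params, bundle, aux = NULL,
                            config = objective_config()) {
  tryCatch(
    sum(residual_blocks(params, bundle, aux, config)$residual^2),
    tscmkin_infeasible = function(e) Inf
  )
}
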