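#' Compare the five lineage models on one donor's study
#'
#' Fits every requested model to the same calibrated bundle and auxiliary
#' cohorts and tabulates the joint objectives. The independent models A and
#' B keep the antigen-specific pool constant after vaccination, so they are
#' flagged as structurally unable to produce a declining vaccine-specific
#' frequency whatever their parameters.
#'
#' @param bundle A calibrated [study_bundle()].
#' @param aux An [aux_data()] object.
#' @param models Character vector of model ids (default all five).
#' @param n_starts,master_seed,maxit Passed to [fit_kinetic_model()].
#' @param config An [objective_config()].
#' @return A tibble with one row per model: `model`, `objective`, `n_par`,
#'   `yfv_decline` (can the model produce a declining vaccine-specific
#'   frequency?), `converged`, `note`, plus a `fits` list-column of the
#'   underlying `tscm_fit` objects.
#' @export
compare_models <- function(bundle, aux, models = c("A", "B", "C", "D", "E"),
                           n_starts = 30, master_seed = 1, maxit = 500,
                           config = objective_config()) {
  rows <- purrr::map(models, function(m) {
    fit <- tryCatch(
      fit_kinetic_model(bundle, aux, model = m, n_starts = n_starts,
                        master_seed = master_seed, maxit = maxit,
                        config = config),
      error = function(e) e)
    if (inherits(fit, "error")) {
      tibble::tibble(model = m, objective = NA_real_, n_par = NA_integer_,
                     yfv_decline = !(m %in% c("A", "B")),
                     converged = FALSE, note = conditionMessage(fit),
                     fits = list(NULL))
    } else {
      tibble::tibble(model = m, objective = fit$objective,
                     n_par = length(fit$par),
                     yfv_decline = !(m %in% c("A", "B")),
                     converged = fit$convergence == 0, note = "",
                     fits = list(fit))
    }
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$objective)
}
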