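#' Bundle one donor's labelling study
#'
#' Collects the per-donor time series a labelling study produces - saliva
#' enrichment, monocyte DNA enrichment, and DNA enrichment of the three
#' sorted T-cell subsets - together with the donor's pool-size ratios.
#' Calibration results ([fit_saliva()], [fit_monocyte()]) are attached by
#' [calibrate_study()].
#'
#' @param donor_id Donor label.
#' @param saliva Tibble with `day`, `enrichment`.
#' @param monocyte Tibble with `day`, `enrichment` and optionally `sd`.
#' @param labels Tibble with `day`, `population` (`"T_N"`, `"CD95int"`,
#'   `"CD95hi"`), `enrichment` and optionally `sd`.
#' @param R_1,R_2 Pool-size ratios CD95int/T_N and CD95hi/T_N.
#' @return A `study_bundle` object.
#' @export
study_bundle <- function(donor_id, saliva, monocyte, labels, R_1, R_2) {
  saliva <- check_series(saliva, c("day", "enrichment"), "saliva series")
  monocyte <- check_series(monocyte, c("day", "enrichment"), "monocyte series")
  if (!is.data.frame(labels)) rlang::abort("labels must be a data frame")
  missing <- setdiff(c("day", "population", "enrichment"), names(labels))
  if (length(missing)) {
    rlang::abort(paste0("labels table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  labels <- tibble::as_tibble(labels)
  bad <- setdiff(unique(labels$population), c("T_N", "CD95int", "CD95hi"))
  if (length(bad)) {
    rlang::abort(paste0("unknown population label(s): ", paste(bad, collapse = ", ")))
  }
  if (!is.finite(R_1) || !is.finite(R_2) || R_1 <= 0 || R_2 <= 0) {
    rlang::abort("pool ratios R_1, R_2 must be positive")
  }
  structure(
    list(donor_id = donor_id, saliva = saliva, monocyte = monocyte,
         labels = labels, R_1 = R_1, R_2 = R_2,
         saliva_fit = NULL, monocyte_fit = NULL),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("Labelling study bundle for donor %s\n", x$donor_id))
  cat(sprintf("  saliva: %d points; monocyte: %d points; labels: %d points (3 pools)\n",
              nrow(x$saliva), nrow(x$monocyte), nrow(x$labels)))
  cat(sprintf("  pool ratios R_1 = %.4g, R_2 = %.4g\n", x$R_1, x$R_2))
  if (!is.null(x$monocyte_fit)) {
    cat(sprintf("  calibrated: f = %.4g, delta = %.4g, b_w = %.4g\n",
                x$saliva_fit$model$f, x$saliva_fit$model$delta,
                x$monocyte_fit$params$b_w))
  } else cat("  not yet calibrated\n")
  invisible(x)
}

#' Auxiliary cohort data shared across donors
#'
#' The telomere and vaccine cohorts come from different individuals than
#' the labelled donors; each labelled donor's kinetic parameters are used
#' to predict these shared observations during joint fitting.
#'
#' @param telomere Tibble with `age_years` and `theta_bp` (observed
#'   T_N-minus-T_SCM mean telomere-length difference).
#' @param yfv Tibble with `years` (since vaccination), `freq_cd8`
#'   (antigen-specific total T_SCM frequency, % of CD8) and logical
#'   `multiple_vaccination`.
#' @return An `aux_data` object.
#' @export
aux_data <- function(telomere, yfv) {
  telomere <- tibble::as_tibble(telomere)
  yfv <- tibble::as_tibble(yfv)
  need_t <- setdiff(c("age_years", "theta_bp"), names(telomere))
  if (length(need_t)) {
    rlang::abort(paste0("telomere table is missing: ", paste(need_t, collapse = ", ")))
  }
  need_y <- setdiff(c("years", "freq_cd8"), names(yfv))
  if (length(need_y)) {
    rlang::abort(paste0("yfv table is missing: ", paste(need_y, collapse = ", ")))
  }
  if (any(yfv$years <= 0)) rlang::abort("yfv `years` must be positive")
  if (any(yfv$freq_cd8 < 0)) rlang::abort("yfv frequencies must be non-negative")
  if (!"multiple_vaccination" %in% names(yfv)) yfv$multiple_vaccination <- FALSE
  structure(list(telomere = telomere, yfv = yfv), class = "aux_data")
}

#' Calibrate a study bundle (saliva then monocyte)
#'
#' Runs the two calibration steps that precede any kinetic-model fitting:
#' estimate the body-water availability parameters from the saliva series,
#' then the amplification factor `b_w` (and blood turnover `r2`) from the
#' monocyte series.
#'
#' @param bundle A [study_bundle()].
#' @param t_switch,t_end Protocol days (defaults 1 and 49).
#' @param m_over_b,delay Fixed monocyte constants (2.6, 1.6 days).
#' @param weighted Weight calibration fits by analytic SDs when available.
#' @return The bundle with `$saliva_fit`, `$monocyte_fit` and `$b_w` set.
#' @export
calibrate_study <- function(bundle, t_switch = 1, t_end = 49,
                            m_over_b = 2.6, delay = 1.6, weighted = FALSE) {
  stopifnot(inherits(bundle, "study_bundle"))
  bundle$saliva_fit <- fit_saliva(bundle$saliva, t_switch, t_end)
  bundle$monocyte_fit <- fit_monocyte(bundle$monocyte, bundle$saliva_fit,
                                      m_over_b = m_over_b, delay = delay,
                                      weighted = weighted)
  bundle$b_w <- bundle$monocyte_fit$params$b_w
  bundle
}
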