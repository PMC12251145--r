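#' Bootstrap uncertainty for a fitted lineage model
#'
#' Nonparametric bootstrap of the joint fit: within each data type
#' (labelling rows, telomere donors, vaccine-cohort rows) the observation
#' rows are resampled with replacement to a dataset of the same size, the
#' model is refitted, and the derived clonal half-lives are recomputed per
#' replicate. Medians and interquartile ranges over replicates are
#' reported; half-lives are summarized from the replicate parameter sets
#' rather than from the point estimates because the parameters are
#' correlated.
#'
#' Refits are warm-started from the point estimate plus `n_starts - 1`
#' random restarts, all drawn from a stream seeded by `master_seed`, so the
#' summary is reproducible bit-for-bit.
#'
#' @param fit A `tscm_fit` from [fit_kinetic_model()] (joint data mode).
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param n_starts Restarts per replicate including the warm start
#'   (default 30, matching the published refitting procedure; scale down
#'   for quick checks).
#' @param master_seed Integer seed.
#' @param maxit Nelder-Mead iteration cap per restart (default 300).
#' @return A `tscm_boot` object: `$replicates` (one row per successful
#'   replicate: parameters, half-lives, objective), `$summary` (term,
#'   median, q25, q75), `$n_failed`. Supports [tidy()] and [glance()].
#' @export
bootstrap_fit <- function(fit, n_boot = 100, n_starts = 30, master_seed = 1,
                          maxit = 300) {
  stopifnot(inherits(fit, "tscm_fit"))
  if (fit$data_mode != "all") {
    rlang::abort("bootstrap is defined for the joint fit (data_mode = 'all')")
  }
  bundle <- fit$bundle
  aux <- fit$aux
  spec <- fit$spec
  z_hat <- spec_to_z(fit$par, spec)
  npar <- length(spec)

  replicate_seeds <- withr::with_seed(master_seed,
                                      sample.int(.Machine$integer.max, n_boot))

  one_rep <- function(r) {
    withr::with_seed(replicate_seeds[r], {
      b <- bundle
      b$labels <- dplyr::slice_sample(bundle$labels, prop = 1, replace = TRUE)
      a <- aux
      a$telomere <- dplyr::slice_sample(aux$telomere, prop = 1, replace = TRUE)
      a$yfv <- dplyr::slice_sample(aux$yfv, prop = 1, replace = TRUE)

      obj_fun <- objective_closure(b, a, fit$config)
      obj_z <- function(z) {
        if (any(!is.finite(z))) return(Inf)
        x <- spec_from_z(z, spec)
        val <- tryCatch(
          obj_fun(materialize_params(x, fit$model, b, fit$data_mode)),
          tscmkin_infeasible = function(e) Inf)
        if (!is.finite(val)) Inf else val
      }
      zs <- list(z_hat)
      for (i in seq_len(n_starts - 1)) {
        for (try in 1:200) {
          z <- qlogis(runif(npar, 0.02, 0.98))
          if (is.finite(obj_z(z))) { zs <- c(zs, list(z)); break }
        }
      }
      best <- NULL
      for (z0 in zs) {
        opt <- polish_z(z0, obj_z, maxit)
        if (is.null(best) || opt$value < best$value) best <- opt
      }
      if (!is.finite(best$value)) return(NULL)
      x <- spec_from_z(best$par, spec)
      params <- materialize_params(x, fit$model, b, fit$data_mode)
      row <- tibble::as_tibble_row(as.list(x))
      row$objective <- best$value
      if (fit$model %in% c("C", "D", "E")) {
        hl <- clonal_half_lives(params)
        row$half_life_int <- hl$half_life_days[hl$population == "CD95int"]
        row$half_life_hi <- hl$half_life_days[hl$population == "CD95hi"]
      }
      row
    })
  }

  reps <- purrr::map(seq_len(n_boot), function(r) {
    tryCatch(one_rep(r), error = function(e) NULL)
  })
  failed <- sum(vapply(reps, is.null, logical(1)))
  reps <- dplyr::bind_rows(reps)
  if (nrow(reps) == 0) rlang::abort("every bootstrap replicate failed to fit")

  terms <- setdiff(names(reps), "objective")
  summary <- purrr::map_dfr(terms, function(tm) {
    q <- quantile(reps[[tm]], c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    tibble::tibble(term = tm, median = q[2], q25 = q[1], q75 = q[3])
  })

  structure(list(
    replicates = reps, summary = summary, n_boot = n_boot,
    n_failed = failed, master_seed = master_seed, model = fit$model,
    donor_id = fit$donor_id
  ), class = "tscm_boot")
}

#' @export
print.tscm_boot <- function(x, ...) {
  cat(sprintf("Bootstrap summary, model %s, donor %s (%d replicates, %d failed)\n",
              x$model, x$donor_id, x$n_boot, x$n_failed))
  print(x$summary)
  invisible(x)
}

#' @rdname bootstrap_fit
#' @param x A `tscm_boot` object.
#' @param ... Unused.
#' @export
tidy.tscm_boot <- function(x, ...) x$summary

#' @rdname bootstrap_fit
#' @export
glance.tscm_boot <- function(x, ...) {
  tibble::tibble(model = x$model, donor_id = x$donor_id,
                 n_boot = x$n_boot, n_failed = x$n_failed,
                 failure_rate = x$n_failed / x$n_boot,
                 master_seed = x$master_seed)
}
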