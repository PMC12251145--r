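#' Read a labelling study from CSV tables
#'
#' Loads the tidy CSV schema the pipeline exchanges: `saliva.csv`
#' (`donor_id, day, enrichment`), `monocyte.csv` (`donor_id, day,
#' enrichment, sd`), `labels.csv` (`donor_id, day, population, enrichment,
#' sd`), `constants.csv` (`donor_id, R_1, R_2`), `telomere.csv`
#' (`age_years, theta_bp`) and `yfv.csv` (`years, freq_cd8,
#' multiple_vaccination`). Schema violations are reported with the file
#' and column name.
#'
#' @param dir Directory containing the CSV files.
#' @return A list with `bundles` (named list of [study_bundle()], one per
#'   donor) and `aux` (an [aux_data()], or `NULL` when the cohort files
#'   are absent).
#' @export
read_study_tables <- function(dir) {
  read_checked <- function(file, cols, optional = FALSE) {
    path <- file.path(dir, file)
    if (!file.exists(path)) {
      if (optional) return(NULL)
      rlang::abort(sprintf("missing input file: %s", path))
    }
    x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(cols, names(x))
    if (length(missing)) {
      rlang::abort(sprintf("%s: missing column(s) %s", file,
                           paste(missing, collapse = ", ")))
    }
    x
  }
  saliva <- read_checked("saliva.csv", c("donor_id", "day", "enrichment"))
  monocyte <- read_checked("monocyte.csv", c("donor_id", "day", "enrichment"))
  labels <- read_checked("labels.csv", c("donor_id", "day", "population", "enrichment"))
  constants <- read_checked("constants.csv", c("donor_id", "R_1", "R_2"))

  bundles <- lapply(constants$donor_id, function(id) {
    study_bundle(
      id,
      saliva = dplyr::select(dplyr::filter(saliva, .data$donor_id == id), -"donor_id"),
      monocyte = dplyr::select(dplyr::filter(monocyte, .data$donor_id == id), -"donor_id"),
      labels = dplyr::select(dplyr::filter(labels, .data$donor_id == id), -"donor_id"),
      R_1 = constants$R_1[constants$donor_id == id],
      R_2 = constants$R_2[constants$donor_id == id]
    )
  })
  names(bundles) <- constants$donor_id

  telomere <- read_checked("telomere.csv", c("age_years", "theta_bp"), optional = TRUE)
  yfv <- read_checked("yfv.csv", c("years", "freq_cd8"), optional = TRUE)
  aux <- if (!is.null(telomere) && !is.null(yfv)) aux_data(telomere, yfv) else NULL
  list(bundles = bundles, aux = aux)
}

#' Write a labelling study to CSV tables
#'
#' Inverse of [read_study_tables()]; values round-trip at full double
#' precision.
#'
#' @param bundles A list of [study_bundle()] objects (or a single bundle).
#' @param aux Optional [aux_data()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_tables <- function(bundles, aux = NULL, dir) {
  if (inherits(bundles, "study_bundle")) bundles <- list(bundles)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, file) readr::write_csv(x, file.path(dir, file))
  with_id <- function(b, tab) dplyr::mutate(b[[tab]], donor_id = b$donor_id, .before = 1)
  wr(purrr::map_dfr(bundles, with_id, "saliva"), "saliva.csv")
  wr(purrr::map_dfr(bundles, with_id, "monocyte"), "monocyte.csv")
  wr(purrr::map_dfr(bundles, with_id, "labels"), "labels.csv")
  wr(purrr::map_dfr(bundles, function(b) {
    tibble::tibble(donor_id = b$donor_id, R_1 = b$R_1, R_2 = b$R_2)
  }), "constants.csv")
  if (!is.null(aux)) {
    wr(aux$telomere, "telomere.csv")
    wr(aux$yfv, "yfv.csv")
  }
  invisible(dir)
}

#' Write a fit report (parameter table + JSON)
#'
#' Emits a parameter table shaped like the published per-donor summary
#' (proliferation and differentiation rates, burst exponent, initial
#' antigen-specific frequency, clonal half-lives) as CSV, plus a JSON
#' report carrying objectives, seeds and bootstrap summaries for
#' reproducibility.
#'
#' @param fits A list of `tscm_fit` objects (or one).
#' @param boots Optional list of matching `tscm_boot` objects.
#' @param dir Output directory.
#' @return The parameter table, invisibly.
#' @export
write_fit_report <- function(fits, boots = NULL, dir) {
  if (inherits(fits, "tscm_fit")) fits <- list(fits)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- purrr::map_dfr(fits, fit_parameter_row)
  readr::write_csv(tab, file.path(dir, "parameters.csv"))
  report <- purrr::map(fits, function(f) {
    list(donor_id = f$donor_id, model = f$model, objective = f$objective,
         master_seed = f$master_seed, n_starts = f$n_starts,
         data_mode = f$data_mode, estimates = as.list(f$par))
  })
  if (!is.null(boots)) {
    if (inherits(boots, "tscm_boot")) boots <- list(boots)
    report <- list(fits = report,
                   bootstrap = purrr::map(boots, function(b) {
                     list(donor_id = b$donor_id, model = b$model,
                          n_boot = b$n_boot, n_failed = b$n_failed,
                          master_seed = b$master_seed,
                          summary = b$summary)
                   }))
  }
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(tab)
}

fit_parameter_row <- function(f) {
  row <- tibble::as_tibble_row(as.list(f$par))
  row <- dplyr::mutate(row, donor_id = f$donor_id, model = f$model,
                       objective = f$objective, .before = 1)
  if (inherits(f$params, "kinetic_params") && f$params$model %in% c("C", "D", "E")) {
    hl <- clonal_half_lives(f$params)
    row$half_life_int_days <- hl$half_life_days[hl$population == "CD95int"]
    row$half_life_hi_days <- hl$half_life_days[hl$population == "CD95hi"]
  }
  row
}

#' Run the full pipeline on one or more studies
#'
#' End-to-end driver: calibrate each donor's bundle (saliva, then
#' monocyte), fit the requested lineage models jointly to labelling +
#' telomere + vaccine data, optionally bootstrap the preferred model, and
#' return (and optionally write) the parameter table.
#'
#' @param bundles A [study_bundle()] or list of them.
#' @param aux An [aux_data()].
#' @param models Models to fit per donor (default `"D"`).
#' @param n_starts,master_seed,maxit Optimizer settings.
#' @param n_boot Bootstrap replicates for the first model (0 = skip).
#' @param out_dir Optional directory for [write_fit_report()] output.
#' @param config An [objective_config()].
#' @return A list: `fits` (nested per donor), `boots`, `table`
#'   (parameter rows per donor x model).
#' @export
run_study <- function(bundles, aux, models = "D", n_starts = 10,
                      master_seed = 1, maxit = 400, n_boot = 0,
                      out_dir = NULL, config = objective_config()) {
  if (inherits(bundles, "study_bundle")) bundles <- list(bundles)
  fits <- list(); boots <- list()
  for (b in bundles) {
    b <- calibrate_study(b)
    for (m in models) {
      f <- fit_kinetic_model(b, aux, model = m, n_starts = n_starts,
                             master_seed = master_seed, maxit = maxit,
                             config = config)
      fits[[paste(b$donor_id, m, sep = ".")]] <- f
    }
    if (n_boot > 0) {
      f0 <- fits[[paste(b$donor_id, models[1], sep = ".")]]
      boots[[b$donor_id]] <- bootstrap_fit(f0, n_boot = n_boot,
                                           master_seed = master_seed)
    }
  }
  tab <- purrr::map_dfr(fits, fit_parameter_row)
  if (!is.null(out_dir)) {
    write_fit_report(fits, if (length(boots)) boots else NULL, out_dir)
  }
  list(fits = fits, boots = if (length(boots)) boots else NULL, table = tab)
}
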