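#' Design of a synthetic labelling study
#'
#' Describes the measurement design the generators emulate: a heavy-water
#' protocol with a full-dose loading day and half dose to day 49, blood
#' sampling during and after labelling up to day 140 with 4 analytic GC/MS
#' replicates per DNA point, a cross-sectional vaccine cohort of 37 donors
#' spanning 0.27-35.02 years post-vaccination, and a telomere cohort of 5
#' donors.
#'
#' @param label_days Days at which sorted-subset (and monocyte) DNA is
#'   sampled.
#' @param saliva_days Days at which saliva is sampled.
#' @param t_switch,t_end Protocol days (1, 49).
#' @param replicates Analytic replicates per DNA point (4).
#' @param label_noise_sd Per-replicate Gaussian SD of DNA M+1 measurements
#'   (default 5e-4, the order of GC/MS analytic variance).
#' @param saliva_noise_sd Gaussian SD of saliva enrichment (default 2e-4).
#' @param yfv_n Vaccine cohort size (37).
#' @param yfv_range_years Sampling window, years post-vaccination.
#' @param yfv_noise_sdlog Lognormal (sdlog) measurement noise on
#'   frequencies (default 0.3).
#' @param yfv_pool_frac Mean subset sizes as a fraction of CD8
#'   (CD95int, CD95hi); donor-level lognormal variation `pool_frac_sdlog`
#'   around these creates the between-individual variation that
#'   within-subset quantification removes.
#' @param pool_frac_sdlog Donor-level sdlog of subset sizes (default 0.5).
#' @param n_multiple_vaccinated,n_low_frequency Donors flagged as multiple
#'   vaccinees (4) / low-frequency (3).
#' @param telomere_n Telomere cohort size (5).
#' @param telomere_age_range Donor ages, years.
#' @param telomere_noise_sd Gaussian SD of observed theta (bp, default 150).
#' @return A list of class `study_design`.
#' @export
study_design <- function(label_days = c(5, 10, 21, 35, 49, 63, 84, 105, 126, 140),
                         saliva_days = c(0.5, 1, 2, 4, 7, 10, 14, 21, 28, 35,
                                         42, 49, 56, 63, 77, 91, 105, 119, 133, 140),
                         t_switch = 1, t_end = 49, replicates = 4,
                         label_noise_sd = 5e-4, saliva_noise_sd = 2e-4,
                         yfv_n = 37, yfv_range_years = c(0.27, 35.02),
                         yfv_noise_sdlog = 0.3,
                         yfv_pool_frac = c(CD95int = 0.015, CD95hi = 0.005),
                         pool_frac_sdlog = 0.5,
                         n_multiple_vaccinated = 4, n_low_frequency = 3,
                         telomere_n = 5, telomere_age_range = c(29, 83),
                         telomere_noise_sd = 150) {
  stopifnot(all(label_days >= 0), all(saliva_days >= 0),
            replicates >= 1, label_noise_sd >= 0, saliva_noise_sd >= 0,
            yfv_n >= 1, telomere_n >= 1)
  structure(as.list(environment()), class = "study_design")
}

#' Default simulation truth
#'
#' A model-D parameter set mirroring the central published estimates for
#' the three pools (naive proliferation 3.1e-4/day, CD95int 8e-4/day,
#' CD95hi 2e-3/day, inter-subset differentiation 1e-3/day, burst exponent
#' 10.3, antigen-specific seed 0.03% of CD8), with the naive
#' differentiation rate set to 1e-6/day - large enough to leave a visible
#' labelling footprint over a 140-day study - and plausible pool ratios
#' R_1 = 0.05, R_2 = 0.01.
#'
#' @return A model-D [kinetic_params()].
#' @export
default_true_params <- function() {
  kinetic_params("D", p_N = 0.00031, p_1 = 0.0008, p_2 = 0.002,
                 R_1 = 0.05, R_2 = 0.01,
                 delta_N = 1e-6, delta_1 = 0.001, k = 10.3, A = 0.03)
}

#' @rdname default_true_params
#' @return `default_saliva_truth()`: a [saliva_model()] with plateau 0.015
#'   and body-water turnover 0.06/day.
#' @export
default_saliva_truth <- function() saliva_model(f = 0.015, delta = 0.06)

#' Generate one donor's synthetic labelling study
#'
#' Simulates the complete measurement bundle of one labelled donor from a
#' known truth: saliva enrichment with additive Gaussian noise, and
#' monocyte plus three sorted-subset DNA enrichment series built from the
#' forward models, each measured as the mean of `replicates` noisy analytic
#' replicates with the per-point SD recorded from those replicates. Pure
#' function of (truth, design, seed).
#'
#' @param true_params A feasible [kinetic_params()] truth.
#' @param saliva_truth A [saliva_model()] truth.
#' @param b_w_truth Amplification factor truth (default 5).
#' @param r2_truth Blood-monocyte disappearance rate truth (default 0.3).
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @param donor_id Donor label.
#' @return A [study_bundle()] (uncalibrated).
#' @export
generate_study <- function(true_params, saliva_truth = default_saliva_truth(),
                           b_w_truth = 5, r2_truth = 0.3,
                           design = study_design(), seed = 1,
                           donor_id = "SIM01") {
  stopifnot(inherits(true_params, "kinetic_params"),
            inherits(design, "study_design"))
  if (true_params$model != "B") equilibrium_loss_rates(true_params)  # reject infeasible truth
  withr::with_seed(seed, {
    saliva_clean <- saliva_enrichment(design$saliva_days, saliva_truth)
    saliva <- tibble::tibble(
      day = design$saliva_days,
      enrichment = saliva_clean + rnorm(length(saliva_clean), 0, design$saliva_noise_sd))

    noisy_points <- function(clean, sd_rep) {
      reps <- matrix(rnorm(length(clean) * design$replicates, mean = clean,
                           sd = sd_rep),
                     nrow = length(clean))
      list(mean = rowMeans(reps), sd = apply(reps, 1, sd))
    }

    mono_clean <- monocyte_trajectory(
      design$label_days, monocyte_params(b_w_truth, r2_truth), saliva_truth)$enrichment
    mono <- noisy_points(mono_clean, design$label_noise_sd)
    monocyte <- tibble::tibble(day = design$label_days,
                               enrichment = mono$mean, sd = mono$sd)

    lab_clean <- label_trajectories(true_params, saliva_truth, b_w_truth,
                                    design$label_days)
    lab <- noisy_points(lab_clean$enrichment, design$label_noise_sd)
    labels <- tibble::tibble(day = lab_clean$day,
                             population = lab_clean$population,
                             enrichment = lab$mean, sd = lab$sd)

    study_bundle(donor_id, saliva, monocyte, labels,
                 R_1 = true_params$R_1, R_2 = true_params$R_2)
  })
}

#' Generate a synthetic cross-sectional vaccine cohort
#'
#' Donors are sampled log-uniformly over the post-vaccination window (the
#' design's range), and each contributes both T_SCM subsets. Subset
#' frequencies within CD8 follow the truth's clone-decay trajectories with
#' multiplicative lognormal measurement noise; within-subset frequencies
#' divide by a donor-specific subset size (lognormal around the design
#' means), so between-donor subset-size variation inflates the %-of-CD8
#' values but cancels in the within-subset quantification. The design's
#' number of multiple-vaccination donors (frequencies boosted 1.5-fold)
#' and of lowest-total-frequency donors are flagged.
#'
#' @param true_params A model C/D/E [kinetic_params()] with `A` set (models
#'   A/B give a flat cohort).
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @param noise Set `FALSE` to place the cohort exactly on the model
#'   trajectories.
#' @return A tibble: `donor`, `years`, `subset`, `freq_cd8`,
#'   `freq_subset`, `multiple_vaccination`, `low_frequency`.
#' @export
generate_yfv_cohort <- function(true_params, design = study_design(),
                                seed = 1, noise = TRUE) {
  stopifnot(inherits(true_params, "kinetic_params"),
            inherits(design, "study_design"))
  withr::with_seed(seed, {
    n <- design$yfv_n
    lr <- log10(design$yfv_range_years)
    years <- sort(10^runif(n, lr[1], lr[2]))
    tr <- yfv_frequency(true_params, years * DAYS_PER_YEAR)
    multiple <- seq_len(n) %in% sample.int(n, design$n_multiple_vaccinated)
    boost <- ifelse(multiple, 1.5, 1)

    per_subset <- function(clean, subset) {
      meas <- clean * boost
      if (noise) meas <- meas * rlnorm(n, 0, design$yfv_noise_sdlog)
      pool <- design$yfv_pool_frac[[subset]]
      pool_donor <- if (noise) pool * rlnorm(n, 0, design$pool_frac_sdlog) else rep(pool, n)
      tibble::tibble(
        donor = sprintf("YF%02d", seq_len(n)), years = years, subset = subset,
        freq_cd8 = meas * pool_donor / pool,
        freq_subset = meas / pool,
        multiple_vaccination = multiple)
    }
    cohort <- dplyr::bind_rows(per_subset(tr$T_int, "CD95int"),
                               per_subset(tr$T_hi, "CD95hi"))
    totals <- tapply(cohort$freq_cd8, cohort$donor, sum)
    low <- names(sort(totals))[seq_len(design$n_low_frequency)]
    cohort$low_frequency <- cohort$donor %in% low
    cohort
  })
}

#' Collapse a subset-resolved vaccine cohort to total T_SCM frequencies
#'
#' The joint fit uses the antigen-specific *total* T_SCM frequency (% of
#' CD8); this sums the two subsets per donor.
#'
#' @param cohort Output of [generate_yfv_cohort()].
#' @return Tibble with `donor`, `years`, `freq_cd8`, `multiple_vaccination`.
#' @export
yfv_totals <- function(cohort) {
  cohort |>
    dplyr::group_by(.data$donor, .data$years, .data$multiple_vaccination) |>
    dplyr::summarise(freq_cd8 = sum(.data$freq_cd8), .groups = "drop") |>
    dplyr::arrange(.data$years)
}

#' Generate a synthetic telomere cohort
#'
#' Observed T_N-minus-T_SCM telomere-length differences for `telomere_n`
#' donors with ages drawn uniformly over the design's range, equal to the
#' truth's predicted theta (age-dependent for models A/B, the equilibrium
#' value otherwise) plus Gaussian noise.
#'
#' @param true_params A [kinetic_params()] truth.
#' @param design A [study_design()].
#' @param settings A [telomere_settings()] (bp per division etc.).
#' @param seed Integer seed.
#' @param noise Set `FALSE` for exact theta observations.
#' @return Tibble with `donor`, `age_years`, `theta_bp`.
#' @export
generate_telomere_cohort <- function(true_params, design = study_design(),
                                     settings = telomere_settings(),
                                     seed = 1, noise = TRUE) {
  withr::with_seed(seed, {
    ages <- sort(runif(design$telomere_n, design$telomere_age_range[1],
                       design$telomere_age_range[2]))
    theta <- vapply(ages, function(a) {
      s <- settings
      if (true_params$model %in% c("A", "B")) s$age_for_AB_years <- a
      telomere_theta(true_params, s)
    }, numeric(1))
    if (noise) theta <- theta + rnorm(length(ages), 0, design$telomere_noise_sd)
    tibble::tibble(donor = sprintf("TL%02d", seq_along(ages)),
                   age_years = ages, theta_bp = theta)
  })
}

#' Generate multinomial differentiation counts
#'
#' Fixture generator for the multipotency index: divided cells are
#' allocated to destination phenotypes by a single multinomial draw.
#'
#' @param true_proportions Named probability vector over destination
#'   phenotypes (sums to 1).
#' @param n_cells Number of divided cells.
#' @param seed Integer seed.
#' @return Named integer vector of counts.
#' @export
generate_differentiation_counts <- function(true_proportions, n_cells, seed = 1) {
  stopifnot(abs(sum(true_proportions) - 1) < 1e-8, n_cells >= 1)
  withr::with_seed(seed, {
    counts <- rmultinom(1, n_cells, true_proportions)[, 1]
    setNames(as.integer(counts), names(true_proportions))
  })
}
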