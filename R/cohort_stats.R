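#' Multipotency index of a sorted subset's differentiation profile
#'
#' Base-10 entropy of the phenotype distribution among divided cells that
#' changed phenotype, self excluded: `MI = -sum(p_i * log10(p_i))` over
#' destination phenotypes `i != j`. Zero when all differentiated cells end
#' up in a single phenotype; maximal (`log10(n - 1)`) when they spread
#' uniformly over the other phenotypes. Counts and proportions give the
#' same value (proportions are renormalized over the non-self
#' destinations); unobserved destinations contribute 0 (the `x log x -> 0`
#' limit). If no divided cell left the input phenotype the index is
#' undefined and `NA` is returned.
#'
#' @param counts Named (or unnamed) numeric vector of divided-cell counts
#'   or proportions by destination phenotype.
#' @param self Name or index of the input phenotype to exclude; `NULL` if
#'   `counts` already excludes it.
#' @return The multipotency index (dimensionless), or `NA_real_`.
#' @export
#' @examples
#' multipotency_index(c(TCM = 50, TEM = 50, TEMRA = 0, TN = 0, Thi = 0))
multipotency_index <- function(counts, self = NULL) {
  stopifnot(is.numeric(counts))
  if (any(counts < 0)) rlang::abort("counts must be non-negative")
  if (!is.null(self)) {
    if (is.character(self)) {
      if (!self %in% names(counts)) rlang::abort("`self` not found in names(counts)")
      counts <- counts[names(counts) != self]
    } else {
      counts <- counts[-self]
    }
  }
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  p <- counts / tot
  p <- p[p > 0]
  -sum(p * log10(p))
}

#' Self-renewal percentage
#'
#' Percentage of divided cells that kept their input phenotype.
#'
#' @param counts Named numeric vector of divided-cell counts by output
#'   phenotype (including the input phenotype).
#' @param self Name or index of the input phenotype.
#' @return Percentage in \[0, 100\], or `NA_real_` if no cell divided.
#' @export
self_renewal_fraction <- function(counts, self) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  retained <- if (is.character(self)) counts[[self]] else counts[[self]]
  100 * retained / tot
}

#' Relative gene expression from qPCR cycle thresholds
#'
#' Standard `2^-dCT` relative quantification against a housekeeping gene.
#'
#' @param ct_gene,ct_housekeeping Cycle-threshold values (finite;
#'   vectorised).
#' @return Fold expression relative to the housekeeping gene.
#' @export
#' @examples
#' relative_expression(25, 25)   # 1
#' relative_expression(26, 25)   # 0.5
relative_expression <- function(ct_gene, ct_housekeeping) {
  if (any(!is.finite(ct_gene)) || any(!is.finite(ct_housekeeping))) {
    rlang::abort("CT values must be finite")
  }
  2^-(ct_gene - ct_housekeeping)
}

#' Model-independent decline regression of the vaccine cohort
#'
#' Cross-sectional analysis of antigen-specific frequencies quantified
#' *within* each memory subset (which removes between-individual variation
#' in subset sizes): frequencies are log10-transformed and regressed on
#' years since vaccination with a subset-specific slope; the difference
#' between the two subsets' slopes is tested through the interaction term.
#' The default keeps all frequencies and excludes recipients of multiple
#' vaccinations; the variant analysis excludes low-frequency donors and
#' keeps multiple vaccinees.
#'
#' @param cohort Tibble with columns `years`, `subset`, `freq_subset`
#'   (frequency within the subset) and logical flags
#'   `multiple_vaccination`, `low_frequency` (flags default to `FALSE` if
#'   absent).
#' @param exclude_low_frequency Drop donors flagged `low_frequency`
#'   (default `FALSE`).
#' @param include_multiple_vaccinated Keep donors flagged
#'   `multiple_vaccination` (default `FALSE`).
#' @return A `yfv_regression` object: `$slopes` (per-subset log10 slope per
#'   year with SE and p), `$contrast` (slope difference, interaction test),
#'   `$fit` (the underlying `lm`). Supports [tidy()] and [glance()].
#' @export
yfv_decline_regression <- function(cohort, exclude_low_frequency = FALSE,
                                   include_multiple_vaccinated = FALSE) {
  cohort <- tibble::as_tibble(cohort)
  need <- setdiff(c("years", "subset", "freq_subset"), names(cohort))
  if (length(need)) {
    rlang::abort(paste0("cohort is missing column(s): ", paste(need, collapse = ", ")))
  }
  if (!"multiple_vaccination" %in% names(cohort)) cohort$multiple_vaccination <- FALSE
  if (!"low_frequency" %in% names(cohort)) cohort$low_frequency <- FALSE
  if (!include_multiple_vaccinated) cohort <- cohort[!cohort$multiple_vaccination, ]
  if (exclude_low_frequency) cohort <- cohort[!cohort$low_frequency, ]
  if (any(cohort$freq_subset <= 0)) {
    rlang::abort("frequencies must be positive for the log10 transform")
  }
  counts <- table(cohort$subset)
  if (length(counts) != 2 || any(counts < 3)) {
    rlang::abort("need two subsets with at least 3 points each")
  }
  cohort$log_freq <- log10(cohort$freq_subset)
  cohort$subset <- factor(cohort$subset)
  fit <- lm(log_freq ~ years * subset, data = cohort)
  cf <- summary(fit)$coefficients

  lev <- levels(cohort$subset)
  slope1 <- cf["years", ]
  inter <- cf[grep("^years:subset", rownames(cf)), ]
  int_nm <- grep("^years:subset", rownames(cf), value = TRUE)
  slope2_est <- slope1[["Estimate"]] + inter[["Estimate"]]
  V <- vcov(fit)
  slope2_se <- sqrt(V["years", "years"] + V[int_nm, int_nm] +
                    2 * V["years", int_nm])
  slopes <- tibble::tibble(
    subset = lev,
    slope_per_year = c(slope1[["Estimate"]], slope2_est),
    std.error = c(slope1[["Std. Error"]], slope2_se),
    p.value = c(slope1[["Pr(>|t|)"]],
                2 * pnorm(-abs(slope2_est / slope2_se)))
  )
  contrast <- tibble::tibble(
    estimate = inter[["Estimate"]],
    std.error = inter[["Std. Error"]],
    statistic = inter[["t value"]],
    p.value = inter[["Pr(>|t|)"]]
  )
  structure(list(slopes = slopes, contrast = contrast, fit = fit,
                 n = nrow(cohort)),
            class = "yfv_regression")
}

#' @export
print.yfv_regression <- function(x, ...) {
  cat("Cross-sectional decline regression (log10 within-subset frequency vs years)\n")
  print(x$slopes)
  cat(sprintf("slope difference: %.4g per year (p = %.3g), n = %d rows\n",
              x$contrast$estimate, x$contrast$p.value, x$n))
  invisible(x)
}

#' @rdname yfv_decline_regression
#' @param x A `yfv_regression` object.
#' @param ... Unused.
#' @export
tidy.yfv_regression <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$slopes, term = paste0("slope_", .data$subset),
                  .keep = "unused"),
    dplyr::mutate(x$contrast, term = "slope_contrast",
                  estimate = .data$estimate)
  ) |>
    dplyr::select(dplyr::any_of(c("term", "slope_per_year", "estimate",
                                  "std.error", "statistic", "p.value")))
}

#' @rdname yfv_decline_regression
#' @export
glance.yfv_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma, nobs = x$n,
                 p.contrast = x$contrast$p.value)
}

#' Two-group comparison and rank correlation wrappers
#'
#' Thin wrappers over the nonparametric tests used throughout cohort
#' comparisons: paired or unpaired two-tailed Wilcoxon for group
#' differences, Spearman rank correlation for trends. The Wilcoxon uses
#' the exact null distribution for n <= 25 without ties and the normal
#' approximation otherwise.
#'
#' @param x,y Numeric vectors. For `method = "wilcoxon"`, the two groups
#'   (equal length when `paired`); for `"spearman"`, the paired
#'   observations.
#' @param paired Paired Wilcoxon (default `FALSE`).
#' @param method `"wilcoxon"` or `"spearman"`.
#' @return A tibble: `method`, `statistic`, `p.value`, `n`, `estimate`
#'   (Spearman rho, `NA` for Wilcoxon).
#' @export
group_compare <- function(x, y, paired = FALSE,
                          method = c("wilcoxon", "spearman")) {
  method <- match.arg(method)
  if (length(x) < 2 || length(y) < 2) rlang::abort("groups are degenerate (fewer than 2 values)")
  if (paired && length(x) != length(y)) {
    rlang::abort("paired comparison needs equal-length groups")
  }
  if (method == "wilcoxon") {
    if (paired && all(x == y)) {
      # no non-zero differences: no evidence against the null
      return(tibble::tibble(method = "wilcoxon_paired", statistic = 0,
                            p.value = 1, n = 2 * length(x),
                            estimate = NA_real_))
    }
    n <- if (paired) length(x) else min(length(x), length(y))
    ht <- suppressWarnings(
      wilcox.test(x, y, paired = paired, exact = n <= 25, correct = TRUE))
    tibble::tibble(method = if (paired) "wilcoxon_paired" else "wilcoxon",
                   statistic = unname(ht$statistic), p.value = ht$p.value,
                   n = length(x) + length(y), estimate = NA_real_)
  } else {
    if (length(x) != length(y)) rlang::abort("spearman needs paired vectors")
    ht <- suppressWarnings(cor.test(x, y, method = "spearman"))
    tibble::tibble(method = "spearman", statistic = unname(ht$statistic),
                   p.value = ht$p.value, n = length(x),
                   estimate = unname(ht$estimate))
  }
}
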