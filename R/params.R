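#' Kinetic parameters for the T_SCM lineage models
#'
#' Bundles the per-donor rate set for one of five candidate lineage models
#' relating naive CD8+ T cells (T_N) and the two T stem-cell-like memory
#' subpopulations (CD95int, CD95hi):
#'
#' * **A** - independent homogeneous pools;
#' * **B** - independent pools with kinetic heterogeneity (labelled cells
#'   may disappear at rates `dstar_*` different from the population rates);
#' * **C** - forked differentiation: antigen-triggered naive clones burst
#'   `2^k`-fold and a fraction `frac` enters CD95int, the rest CD95hi;
#' * **D** - linear differentiation, CD95int first then CD95hi;
#' * **E** - linear differentiation, CD95hi first then CD95int.
#'
#' All pools are assumed to be of constant size; disappearance rates are
#' derived from that equilibrium (see [equilibrium_loss_rates()]), except in
#' model B where the labelled-cell disappearance rates are free parameters.
#' Fields irrelevant to the chosen model are ignored.
#'
#' @param model One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @param p_N,p_1,p_2 Proliferation rates (per day) of T_N, CD95int, CD95hi.
#' @param R_1,R_2 Pool-size ratios CD95int/T_N and CD95hi/T_N (> 0).
#' @param delta_N Fraction of T_N differentiating per day (models C/D/E).
#' @param delta_1 Differentiation rate between the T_SCM pools (per day;
#'   CD95int to CD95hi in model D, CD95hi to CD95int in model E).
#' @param k Clonal burst-size exponent in \[0, 15\] (burst of `2^k` cells).
#' @param frac Fraction of the burst entering CD95int (model C only).
#' @param dstar_N,dstar_1,dstar_2 Disappearance rates of labelled cells
#'   (model B only).
#' @param A Initial antigen-specific frequency per T_SCM pool (% of CD8;
#'   used by the vaccine-decay observable, where the total starts at `2A`).
#' @return An object of class `kinetic_params`.
#' @export
#' @examples
#' kinetic_params("D", p_N = 3e-4, p_1 = 8e-4, p_2 = 2e-3,
#'                R_1 = 0.05, R_2 = 0.01,
#'                delta_N = 1e-6, delta_1 = 1e-3, k = 10.3, A = 0.03)
kinetic_params <- function(model, p_N, p_1, p_2, R_1, R_2,
                           delta_N = NULL, delta_1 = NULL, k = NULL,
                           frac = NULL, dstar_N = NULL, dstar_1 = NULL,
                           dstar_2 = NULL, A = NULL) {
  model <- match.arg(model, c("A", "B", "C", "D", "E"))
  chk_rate <- function(x, nm, allow_null = FALSE) {
    if (is.null(x)) {
      if (!allow_null) rlang::abort(sprintf("model %s requires `%s`", model, nm))
      return(NULL)
    }
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
      rlang::abort(sprintf("`%s` must be a single non-negative number", nm))
    }
    x
  }
  p_N <- chk_rate(p_N, "p_N"); p_1 <- chk_rate(p_1, "p_1"); p_2 <- chk_rate(p_2, "p_2")
  if (!is.finite(R_1) || !is.finite(R_2) || R_1 <= 0 || R_2 <= 0) {
    rlang::abort("pool ratios R_1 and R_2 must be positive")
  }
  x <- list(model = model, p_N = p_N, p_1 = p_1, p_2 = p_2,
            R_1 = R_1, R_2 = R_2)
  if (model %in% c("C", "D", "E")) {
    x$delta_N <- chk_rate(delta_N, "delta_N")
    x$k <- chk_rate(k, "k")
    if (x$k > 15) rlang::abort("`k` must lie in [0, 15]")
  }
  if (model %in% c("D", "E")) x$delta_1 <- chk_rate(delta_1, "delta_1")
  if (model == "C") {
    x$frac <- chk_rate(frac, "frac")
    if (x$frac > 1) rlang::abort("`frac` must lie in [0, 1]")
  }
  if (model == "B") {
    x$dstar_N <- chk_rate(dstar_N, "dstar_N")
    x$dstar_1 <- chk_rate(dstar_1, "dstar_1")
    x$dstar_2 <- chk_rate(dstar_2, "dstar_2")
  }
  if (!is.null(A)) {
    A <- chk_rate(A, "A", allow_null = TRUE)
    if (A <= 0) rlang::abort("`A` must be positive when supplied")
    x$A <- A
  }
  structure(x, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  flds <- x[setdiff(names(x), "model")]
  cat(sprintf("Kinetic parameters, lineage model %s:\n", x$model))
  cat(paste0("  ", names(flds), " = ", signif(unlist(flds), 4), collapse = "\n"), "\n")
  invisible(x)
}

#' Disappearance rates implied by constant pool sizes
#'
#' Each lineage model assumes the three pools are at equilibrium; setting the
#' cell-number time derivatives to zero expresses the disappearance rates
#' `d_N`, `d_1`, `d_2` in terms of the proliferation and differentiation
#' rates and the pool ratios. Model B fits labelled-cell disappearance rates
#' directly and the population equilibrium does not determine them, so it is
#' rejected here.
#'
#' @param params A [kinetic_params()] object (model A, C, D or E).
#' @return Named numeric vector `c(d_N, d_1, d_2)` (per day).
#'   Signals an error of class `tscmkin_infeasible` if any derived rate is
#'   negative, so optimizers can reject the parameter point.
#' @export
equilibrium_loss_rates <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  p <- params
  d <- switch(p$model,
    A = c(p$p_N, p$p_1, p$p_2),
    B = rlang::abort(
      "model B fits labelled-cell disappearance rates directly; equilibrium does not determine d"),
    C = c(p$p_N - p$delta_N,
          p$p_1 + p$delta_N * p$frac * 2^p$k / p$R_1,
          p$p_2 + p$delta_N * (1 - p$frac) * 2^p$k / p$R_2),
    D = c(p$p_N - p$delta_N,
          p$p_1 + p$delta_N * 2^p$k / p$R_1 - p$delta_1,
          p$p_2 + p$delta_1 * p$R_1 / p$R_2),
    E = c(p$p_N - p$delta_N,
          p$p_1 + p$delta_1 * p$R_2 / p$R_1,
          p$p_2 + p$delta_N * 2^p$k / p$R_2 - p$delta_1)
  )
  names(d) <- c("d_N", "d_1", "d_2")
  if (any(d < 0)) {
    stop_infeasible(sprintf(
      "equilibrium gives a negative disappearance rate (%s); parameter point infeasible",
      paste(names(d)[d < 0], collapse = ", ")))
  }
  d
}

#' Fork-model label-only reparameterization
#'
#' When model C is fitted to labelling data alone, the proliferation rates
#' and burst size are not separately identifiable; the effective label
#' production rates `Pi_1 = p_1 + delta_N * frac * (2^k - 1) / R_1` and
#' `Pi_2 = p_2 + delta_N * (1 - frac) * (2^k - 1) / R_2` are.
#' `fork_reparameterize()` maps a full parameter set to `(Pi_1, Pi_2)`;
#' `fork_invert()` recovers `p_1`, `p_2` given the remaining fields.
#'
#' @param params A model-C [kinetic_params()] object.
#' @return `fork_reparameterize()`: named vector `c(Pi_1, Pi_2)`.
#' @export
fork_reparameterize <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$model != "C") rlang::abort("reparameterization applies to model C only")
  with(params, c(
    Pi_1 = p_1 + delta_N * frac * (2^k - 1) / R_1,
    Pi_2 = p_2 + delta_N * (1 - frac) * (2^k - 1) / R_2
  ))
}

#' @rdname fork_reparameterize
#' @param Pi_1,Pi_2 Effective label production rates (per day).
#' @param template A model-C [kinetic_params()] supplying `delta_N`, `k`,
#'   `frac` and the pool ratios.
#' @return `fork_invert()`: a model-C `kinetic_params` with `p_1`, `p_2`
#'   recovered.
#' @export
fork_invert <- function(Pi_1, Pi_2, template) {
  stopifnot(inherits(template, "kinetic_params"))
  if (template$model != "C") rlang::abort("reparameterization applies to model C only")
  t <- template
  p_1 <- Pi_1 - t$delta_N * t$frac * (2^t$k - 1) / t$R_1
  p_2 <- Pi_2 - t$delta_N * (1 - t$frac) * (2^t$k - 1) / t$R_2
  if (p_1 < 0 || p_2 < 0) {
    stop_infeasible("inverted proliferation rate is negative; (Pi, delta_N, k, frac) infeasible")
  }
  kinetic_params("C", p_N = t$p_N, p_1 = p_1, p_2 = p_2,
                 R_1 = t$R_1, R_2 = t$R_2, delta_N = t$delta_N,
                 k = t$k, frac = t$frac, A = t$A)
}
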