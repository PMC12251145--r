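---
title: "Kinetic modelling of CD8+ T stem-cell-like memory subpopulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of CD8+ T stem-cell-like memory subpopulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tscmkin)
```

## The question and the data

Human CD8+ T stem-cell-like memory cells (T~SCM~, CD45RA+CCR7+CD95+) split
into two subpopulations by CD95 level, CD95int and CD95hi. `tscmkin`
estimates how fast these pools proliferate, differentiate and die *in
vivo*, and how long an antigen-specific clone persists in each, by fitting
compartmental models jointly to three kinds of data:

1. **Stable-isotope labelling**: volunteers drink deuterated water (a
   double dose on day 1, a half dose through day 49), and the M+1
   enrichment of DNA in sorted T~N~, CD95int and CD95hi cells is followed
   to day 140. Dividing cells incorporate deuterium, so enrichment curves
   encode proliferation and turnover.
2. **Telomere lengths**: the difference `theta` (bp) in mean telomere
   length between T~N~ and total T~SCM~ reflects the pools' cumulative
   division histories (50 bp lost per division by default).
3. **Vaccine-induced clone decay**: a cross-sectional cohort measured
   yellow-fever-virus-specific T~SCM~ frequencies 0.27 to 35 years after
   vaccination; its decline constrains the loss of antigen-specific
   clones.

The labelled donors, the telomere donors and the vaccine cohort are
different people: each labelled donor's kinetic parameters are required to
*predict* the two shared cohorts, and those prediction errors enter the
donor's objective.

## Label availability and calibration

Body-water label availability is an empirical three-phase curve: during
the full-dose day enrichment relaxes towards the plateau `f` at the water
turnover rate `delta`; during the half-dose phase towards `f/2`; after
day 49 it decays exponentially. The curve is continuous, `S(0) = 0` and
`S(t) -> 0`. `fit_saliva()` estimates `(f, delta)` per donor by nonlinear
least squares.

DNA made during labelling carries `b_w * S(t)` excess M+1, where the
amplification factor `b_w` maps body-water enrichment to DNA enrichment.
`b_w` is calibrated from blood monocytes — a population that turns over
fast enough to approach full labelling — using a two-compartment marrow /
blood model with a fixed marrow-to-blood ratio (2.6) and post-mitotic
transit time (1.6 days). Because blood monocytes plateau at `b_w * f`,
the `b_w` estimate is insensitive to those two fixed constants, which the
test suite asserts.

## The five lineage models

All models assume each pool is at constant size; this equilibrium
eliminates the disappearance rates (`equilibrium_loss_rates()`), except in
model B where the labelled-cell loss rates are free:

* **A** — three independent, kinetically homogeneous pools;
* **B** — independent pools, labelled cells may die at their own rates;
* **C** — *fork*: naive clones meeting antigen burst to `2^k` cells, a
  fraction `frac` joins CD95int, the rest CD95hi;
* **D** — *linear, CD95int first*: the burst enters CD95int, which feeds
  CD95hi at rate `delta_1`;
* **E** — *linear, CD95hi first*: the mirror image.

Label fractions obey linear ODE systems forced by `b_w * S(t)`. Burst
inflow contributes `delta_N * ((2^k - 1) * b_w * S + L_N) / R` per
recipient cell: a burst of `2^k` cells carries the naive cell's old
strands (label `L_N`) plus `2^k - 1` cells' worth of newly made DNA.

For the linear models the published label equations route the naive burst
inflow directly into the *downstream* pool, which is inconsistent with the
corresponding cell-number equations (where that pool is fed only by the
`delta_1` flux). The package defaults to the mass-balance form —
`L_2` in model D is fed by `delta_1 * (R_1/R_2) * L_1` — and exposes
`as_printed = TRUE` to reproduce the literal published equations; both
variants are oracle-tested.

### Numerical route

Every label system here is linear with constant coefficients, forced by a
piecewise-exponential `S(t)`. Augmenting the state with the phase
exponential and a constant makes the system autonomous, so the solution is
a product of matrix exponentials — exact to `expm()` accuracy (~1e-14),
with no step-size control, and roughly two orders of magnitude faster than
adaptive integration. That speed is what makes the multi-start fits and
bootstrap refits cheap. The test suite integrates the same systems with
`deSolve` (lsoda, rtol 1e-8 / atol 1e-10) as an independent oracle and
requires agreement to 1e-6. The monocyte delay term is handled by
propagating the time-shifted precursor compartment jointly with the blood
compartment, avoiding a general delay-ODE solver.

## Observables

**Telomere difference.** Writing `nu_i` for the excess cumulative
divisions of pool *i* over T~N~, the burst influx pulls `nu` to a linear
steady state; `theta = delta_tel * (w_1 nu_1 + w_2 nu_2)` with pool-ratio
weights `w_i = R_i / (R_1 + R_2)`. For models C–E theta is age-independent
at equilibrium and the package evaluates the closed-form steady state by
default: at realistic naive differentiation rates (order 1e-9 to 1e-6 per
day) the relaxation time of the `nu` system far exceeds any feasible
integration horizon, so numeric integration inside an objective function
would either be wrong or prohibitively long. `method = "ode"` provides the
numeric route (with an explicit non-convergence error) and the tests
cross-check the two on fast-relaxing parameter draws. For the independent
models A/B theta grows linearly with age and is evaluated at 34 years, a
typical median age for telomere cohorts.

**Clone decay.** After vaccination no further naive input is assumed; each
antigen-specific T~SCM~ pool starts at frequency `A` (total `2A`). Models
A/B predict a constant frequency — structurally unable to match a
declining cohort — while C–E give one- or two-exponential decays with
rates `alpha`, `gamma` determined by the kinetic parameters. The removable
`alpha = gamma` singularity in the two-exponential form is evaluated by
its analytic `t * exp(-alpha t)` limit inside a relative tolerance of
1e-9, not left to cancellation.

**Clonal half-lives and residency.** The clonal half-life is
`ln 2 / (net clonal loss)`, e.g. `R_1 ln2 / (delta_N 2^k)` for CD95int in
model D — the persistence of immune memory, as opposed to the cellular
half-life `ln 2 / d`. Residency times are reciprocal total exit rates with
equilibrium-derived disappearance. Zero denominators yield `Inf` rather
than errors.

## Fitting

For each data type the residuals are normalized by the mean of that data
type's observations (labelling counts as one type across the three pools;
`per_pool` normalization is available in `objective_config()`), and the
objective is the total sum of squares. Infeasible parameter points —
those whose equilibrium disappearance rates would be negative — return
`Inf` through a typed condition so optimizers reject them cleanly.

`fit_kinetic_model()` searches a box (rates log-scaled in
[1e-10, 0.5]/day; `k` in [0, 15] — the upper bound implied by fits that
pin the burst exponent at 15; `frac` in [0, 1]; `A` in [1e-4, 1] % of CD8)
by multi-start random search: starting points are drawn from one seeded
stream (rejection-sampled to feasibility), each polished by quasi-Newton
descent (`nlminb`) plus a Nelder–Mead cleanup on a logistic-transformed
scale. The best polished start wins, so results are deterministic given
`master_seed` and the objective is non-increasing in `n_starts`. For
label-only fits of the fork model the identifiable
`(p_N, Pi_1, Pi_2, frac, delta_N)` parameterization is used.

The bootstrap resamples observation rows within each data type (same
counts), refits each replicate from the point estimate plus random
restarts (30 per replicate by default, matching the published refitting
depth), and reports medians and IQRs of parameters *and* derived
half-lives across replicates — half-lives are summarized from replicate
parameter sets because the parameters are strongly correlated along
identifiability ridges.

### Identifiability

At the default truth the CD95int pool's labelling is dominated by the
burst influx, so `p_1` has little leverage; `delta_N` and `k` enter nearly
everywhere as the product `delta_N * 2^k`; and `p_2` trades off against
`delta_1` in the CD95hi balance. These ridges are intrinsic to the design,
which is why uncertainty is reported by bootstrap IQRs over well-explored
refits rather than by local curvature, and why derived quantities such as
clonal half-lives (functions of the identifiable combinations) are much
better determined than individual rates. The parameter-recovery study in
the test suite measures IQR coverage of the generating values across
simulated studies; note an IQR is a 50% interval, so for well-identified
parameters its long-run coverage of the truth is bounded near 50% — high
coverage is expected only where the IQRs are wide.

## The synthetic-study generator

`generate_study()` and its cohort companions emulate the study design: 10
DNA sampling days to day 140 with 4 analytic replicates per point
(per-replicate Gaussian SD 5e-4 M+1 units, the order of GC/MS analytic
variance; the recorded per-point SD is the SD of the 4 replicates), 20
saliva days (additive SD 2e-4), a 37-donor vaccine cohort log-uniform over
0.27–35.02 years with lognormal (sdlog 0.3) measurement noise, donor-level
subset sizes lognormal (sdlog 0.5) around 1.5% / 0.5% of CD8, 4
multiple-vaccination donors (1.5-fold boosted, flagged) and 3
low-total-frequency donors flagged, and a 5-donor telomere cohort aged
29–83 with 150 bp Gaussian noise on theta.

The default truth mirrors the central published estimates (`p_N` 3.1e-4,
`p_1` 8e-4, `p_2` 2e-3 per day, `delta_1` 1e-3 per day, `k` 10.3, `A`
0.03% of CD8) with pool ratios `R_1 = 0.05`, `R_2 = 0.01` (plausible
values; the per-donor ratios are study inputs, not published constants)
and the naive differentiation rate set to 1e-6/day — large enough to
leave a visible labelling footprint over 140 days, where the
nanoscale published estimates would be invisible in a short synthetic
study. Two caveats follow: the vaccine-specific pools then decay much
faster than in real cohorts, and passing recovery tests at this truth
does not demonstrate that `delta_N` of order 1e-9/day could be recovered —
only the wide bootstrap intervals reported for such fits are meaningful
there. Generators are pure functions of (truth, design, seed).

## Test and report scales

The suite runs the oracle checks on ~100 random feasible parameter draws
per stage, the recovery study on three simulated donors (20 bootstrap
replicates × 8 restarts each), the model-selection study on 20 simulated
studies × 5 models (2 restarts each), and the null-calibration study of
the slope-contrast test on 1,000 simulated cohorts; `scripts/acceptance.R`
fits one donor with 10 restarts and a 24-replicate bootstrap. These sizes
are the package's documented defaults for its own checks; production
analyses should use the function defaults (30 restarts, 100 bootstrap
replicates).

## Known limitations

* The equilibrium (constant pool size) assumption is structural; growing
  or shrinking pools are out of scope.
* Model B's labelled-cell loss rates are phenomenological; no explicit
  kinetic substructure is modelled.
* The generator draws measurement noise as independent Gaussians /
  lognormals; real GC/MS series have day-level batch effects it does not
  emulate, so recovery results bound statistical, not systematic, error.
* Donors are fitted independently; no hierarchical sharing of parameters.
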