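# tscmkin

Kinetics of human CD8+ T stem-cell-like memory (T_SCM) subpopulations from
stable-isotope labelling studies.

Human T_SCM cells split by CD95 level into CD95int and CD95hi
subpopulations with very different dynamics. `tscmkin` is for
quantitative immunologists who want to estimate, per donor, how fast the
naive (T_N), CD95int and CD95hi pools proliferate and differentiate *in
vivo*, and how long antigen-specific clones persist in each — the
quantity that matters for the durability of immune memory.

## What it computes

**Calibration.** Body-water deuterium availability over the drinking
protocol (full dose 1 day, half dose to day 49, washout) is the
continuous three-phase curve

    S(t) = f (1 - e^{-delta t})                                   t < 1
           f/2 (1 - e^{-delta (t-1)}) + S(1) e^{-delta (t-1)}     1 <= t <= 49
           S(49) e^{-delta (t-49)}                                t > 49

fitted per donor from saliva (`fit_saliva()`); the amplification factor
`b_w` scaling body-water enrichment to DNA M+1 enrichment is estimated
from blood monocytes via a marrow/blood compartment model
(`fit_monocyte()`).

**Five lineage models** for cell numbers and DNA label in (T_N, CD95int,
CD95hi): independent homogeneous (A), independent heterogeneous (B),
forked differentiation after a clonal burst of 2^k cells (C), and linear
differentiation CD95int-first (D) or CD95hi-first (E). Constant pool
sizes eliminate the disappearance rates, e.g. for model D

    d_N = p_N - Delta_N,  d_1 = p_1 + Delta_N 2^k / R_1 - Delta_1,
    d_2 = p_2 + Delta_1 R_1 / R_2.

Label systems are solved exactly (matrix-exponential propagation of the
piecewise-exponential forcing) and verified against adaptive ODE
integration in the tests.

**Joint fitting** (`fit_kinetic_model()`) minimizes the sum of squared
mean-normalized residuals over labelling, telomere-length-difference and
cross-sectional vaccine-decay data by seeded multi-start search with
quasi-Newton polish; `bootstrap_fit()` gives medians and IQRs of
parameters and derived clonal half-lives, e.g. for model D

    t_half(CD95int clone) = R_1 ln2 / (Delta_N 2^k),
    t_half(CD95hi clone)  = R_2 ln2 / (R_1 Delta_1).

`compare_models()`, `predict_subset_decay()`, `yfv_decline_regression()`
and the cohort statistics (`multipotency_index()`, `group_compare()`, ...)
round out the analysis, and `generate_study()` / `generate_yfv_cohort()` /
`generate_telomere_cohort()` simulate complete studies so the whole
pipeline is testable without any external data.

## Worked example

Simulate one donor's study at the default truth, calibrate, and fit the
linear CD95int-first model jointly to all three data types:

```r
library(tscmkin)
truth  <- default_true_params()
bundle <- generate_study(truth, seed = 42, donor_id = "SIM01")
aux    <- aux_data(
  generate_telomere_cohort(truth, seed = 43),
  yfv_totals(generate_yfv_cohort(truth, seed = 44))
)
bundle <- calibrate_study(bundle)
bundle
#> Labelling study bundle for donor SIM01
#>   saliva: 20 points; monocyte: 10 points; labels: 30 points (3 pools)
#>   pool ratios R_1 = 0.05, R_2 = 0.01
#>   calibrated: f = 0.01522, delta = 0.06275, b_w = 4.899

fit <- fit_kinetic_model(bundle, aux, model = "D", n_starts = 12,
                         master_seed = 1, maxit = 500)
fit
#> Lineage model D fit, donor SIM01 (labelling + telomere + vaccine data)
#>   objective = 54.0795 over 12 restarts (seed 1)
#>   estimates:
#>     p_N = 0.000371
#>     p_1 = 0.022
#>     p_2 = 0.00137
#>     delta_N = 5.4e-05
#>     delta_1 = 0.0013
#>     k = 1.88
#>     A = 0.0174

clonal_half_lives(fit$params)
#> # A tibble: 2 x 2
#>   population half_life_days
#> 1 CD95int              174.
#> 2 CD95hi               107.
```

The calibration recovers the generating truth closely (f 0.0152 vs 0.015,
delta 0.063 vs 0.06, b_w 4.90 vs 5). The naive proliferation rate
(0.00037/day, one division every ~7 years) and `delta_1` (0.0013/day) sit
near their generating values, while `delta_N` and `k` land elsewhere on
the `delta_N * 2^k` ridge they share — individual rates on such ridges
are reported with their bootstrap IQRs (`bootstrap_fit(fit)`), which is
also how the derived clonal half-lives should be read. `autoplot(fit)`
overlays the fitted enrichment curves on the data.

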