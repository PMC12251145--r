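# shared small synthetic study (built once per test file load)
ts <- make_test_study(seed = 11)

test_that("joint objective: zero at generating truth on noiseless data, scale-invariant blocks, row-order invariant", {
  truth <- ts$truth
  # noiseless bundle: regenerate with zero noise and calibrate exactly
  design0 <- study_design(label_noise_sd = 0, saliva_noise_sd = 0)
  b0 <- calibrate_study(generate_study(truth, b_w_truth = 5, design = design0, seed = 1))
  aux0 <- aux_data(generate_telomere_cohort(truth, seed = 2, noise = FALSE),
                   yfv_totals(generate_yfv_cohort(truth, seed = 3, noise = FALSE)))
  expect_lt(joint_objective(truth, b0, aux0), 1e-6)

  # mean normalization: scaling one data type leaves its block unchanged
  blocks <- residual_blocks(truth, ts$bundle, ts$aux)
  aux_scaled <- ts$aux
  aux_scaled$telomere$theta_bp <- 1000 * aux_scaled$telomere$theta_bp
  # prediction must scale too for the invariance statement: scale delta_tel
  cfg <- objective_config(theta_settings = telomere_settings(delta_tel = 50 * 1000))
  b_tel <- residual_blocks(truth, ts$bundle, aux_scaled, cfg)
  expect_equal(b_tel$residual[b_tel$data_type == "telomere"],
               blocks$residual[blocks$data_type == "telomere"],
               tolerance = 1e-12)

  # row order of observations does not change the objective
  b_shuf <- ts$bundle
  aux_shuf <- ts$aux
  b_shuf$labels <- withr::with_seed(5, dplyr::slice_sample(ts$bundle$labels, prop = 1))
  aux_shuf$yfv <- withr::with_seed(6, dplyr::slice_sample(ts$aux$yfv, prop = 1))
  expect_equal(joint_objective(truth, b_shuf, aux_shuf),
               joint_objective(truth, ts$bundle, ts$aux), tolerance = 1e-12)

  # infeasible parameters give an optimizer-safe +Inf
  bad <- kinetic_params("D", 1e-3, 1e-4, 1e-3, R_1 = 0.05, R_2 = 0.01,
                        delta_N = 1e-8, delta_1 = 0.1, k = 2, A = 0.03)
  expect_identical(joint_objective(bad, ts$bundle, ts$aux), Inf)
})

test_that("a hand-computed toy residual block matches the implementation", {
  # 3-point toy: constant predictions against tiny observation vectors
  b <- ts$bundle
  lab <- b$labels[b$labels$day == b$labels$day[1], ]
  b$labels <- lab
  pred <- label_trajectories(ts$truth, b$saliva_fit$model, b$b_w,
                             unique(lab$day))
  pred <- pred$enrichment[match(lab$population, pred$population)]
  by_hand <- sum(((lab$enrichment - pred) / mean(lab$enrichment))^2)
  blocks <- residual_blocks(ts$truth, b, aux = NULL)
  expect_equal(sum(blocks$residual^2), by_hand, tolerance = 1e-12)
})

test_that("multi-start fit is deterministic, monotone in restarts, and improves on truth's objective", {
  f3 <- fit_kinetic_model(ts$bundle, ts$aux, model = "D", n_starts = 3,
                          master_seed = 21, maxit = 150)
  f3b <- fit_kinetic_model(ts$bundle, ts$aux, model = "D", n_starts = 3,
                           master_seed = 21, maxit = 150)
  expect_identical(f3$par, f3b$par)           # reproducible given the seed
  expect_identical(f3$objective, f3b$objective)

  f5 <- fit_kinetic_model(ts$bundle, ts$aux, model = "D", n_starts = 5,
                          master_seed = 21, maxit = 150)
  expect_lte(f5$objective, f3$objective)      # best-of over a shared prefix
  expect_equal(f5$starts[seq_along(f3$starts)], f3$starts)

  # the polished optimum cannot be worse than the generating parameters
  expect_lte(f5$objective, joint_objective(ts$truth, ts$bundle, ts$aux))

  expect_s3_class(tidy(f5), "tbl_df")
  expect_true(all(c("term", "estimate") %in% names(tidy(f5))))
  expect_equal(glance(f5)$model, "D")
})

test_that("label-only fitting uses the fork reparameterization for model C", {
  f <- fit_kinetic_model(ts$bundle, aux = NULL, model = "C", n_starts = 3,
                         master_seed = 31, maxit = 200,
                         data_mode = "label_only")
  expect_setequal(names(f$par), c("p_N", "Pi_1", "Pi_2", "delta_N", "frac"))
  expect_true(is.finite(f$objective))
  # joint mode needs aux
  expect_error(fit_kinetic_model(ts$bundle, NULL, model = "C"), "aux_data")
})

test_that("bootstrap summaries are reproducible, ordered, and tight on low-noise data", {
  # low-noise study: bootstrap IQRs should be narrow around the point fit
  design_low <- study_design(label_noise_sd = 2e-5, saliva_noise_sd = 1e-5,
                             yfv_noise_sdlog = 0.01, telomere_noise_sd = 2)
  truth <- ts$truth
  b0 <- calibrate_study(generate_study(truth, design = design_low, seed = 41))
  aux0 <- aux_data(generate_telomere_cohort(truth, seed = 42,
                                            design = design_low),
                   yfv_totals(generate_yfv_cohort(truth, seed = 43,
                                                  design = design_low)))
  f0 <- fit_kinetic_model(b0, aux0, model = "D", n_starts = 4,
                          master_seed = 44, maxit = 300)
  bt <- bootstrap_fit(f0, n_boot = 8, n_starts = 2, master_seed = 45,
                      maxit = 200)
  bt2 <- bootstrap_fit(f0, n_boot = 8, n_starts = 2, master_seed = 45,
                       maxit = 200)
  expect_identical(bt$summary, bt2$summary)   # bit-identical given the seed
  expect_true(all(bt$summary$q25 <= bt$summary$median + 1e-12))
  expect_true(all(bt$summary$median <= bt$summary$q75 + 1e-12))
  # low-noise: identifiable rate combinations pinned tightly; check the
  # derived CD95int clonal half-life (an identifiable quantity)
  s <- bt$summary
  hl <- s[s$term == "half_life_int", ]
  expect_lt((hl$q75 - hl$q25) / hl$median, 0.5)
  truth_hl <- truth$R_1 * log(2) / (truth$delta_N * 2^truth$k)
  expect_lt(abs(hl$median / truth_hl - 1), 0.3)
  expect_equal(glance(bt)$n_boot, 8)
})

test_that("model comparison flags the constant-frequency models and orders by objective", {
  cmp <- compare_models(ts$bundle, ts$aux, models = c("A", "D"),
                        n_starts = 2, master_seed = 51, maxit = 150)
  expect_setequal(cmp$model, c("A", "D"))
  expect_false(cmp$yfv_decline[cmp$model == "A"])
  expect_true(cmp$yfv_decline[cmp$model == "D"])
  # the vaccine cohort declines strongly under the model-D truth, which the
  # constant-frequency model A cannot reproduce
  expect_lt(cmp$objective[cmp$model == "D"], cmp$objective[cmp$model == "A"])
  expect_true(all(diff(cmp$objective) >= 0))
})

test_that("subset-resolved decay prediction starts at the early-cohort medians with the fitted rates", {
  cohort <- generate_yfv_cohort(ts$truth, seed = 61)
  f <- fit_kinetic_model(ts$bundle, ts$aux, model = "D", n_starts = 3,
                         master_seed = 62, maxit = 200)
  pred <- predict_subset_decay(f, cohort, horizon_years = 35)
  early <- cohort[cohort$years <= 1, ]
  med_int <- median(early$freq_cd8[early$subset == "CD95int"])
  med_hi <- median(early$freq_cd8[early$subset == "CD95hi"])
  tr0 <- pred$trajectories[pred$trajectories$years == 0, ]
  expect_equal(tr0$frequency[tr0$subset == "CD95int"], med_int)
  expect_equal(tr0$frequency[tr0$subset == "CD95hi"], med_hi)

  # model D: CD95int is a single exponential with rate alpha
  alpha <- f$params$delta_N * 2^f$params$k / f$params$R_1
  tr_int <- pred$trajectories[pred$trajectories$subset == "CD95int", ]
  expect_equal(tr_int$frequency,
               med_int * exp(-alpha * tr_int$years * 365.25),
               tolerance = 1e-10)
  # both subsets decay monotonically
  tr_hi <- pred$trajectories[pred$trajectories$subset == "CD95hi", ]
  expect_true(all(diff(tr_int$frequency) <= 0))
  expect_true(all(diff(tr_hi$frequency) <= 1e-12))

  # no early donors -> informative failure
  late <- cohort[cohort$years > 1, ]
  expect_error(predict_subset_decay(f, late), "within 1 year")
})
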