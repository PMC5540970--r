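p_true <- model_parameters()

test_that("fit_hill exactly recovers a generating triple on noiseless data", {
  doses <- c(5, 2, 1, 0.5, 0.1, 0.05, 0.005, 0.0005)
  tab <- dose_rate_table(doses, hill_response(doses, 4.5, 0.19, 1.48))
  fit <- fit_hill(tab)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates),
               c(4.5, 0.19, 1.48), tolerance = 1e-6)
  expect_lt(fit$sse, 1e-10)
})

test_that("fit_hill is scale-equivariant in the rate axis", {
  tab <- read_dose_rate_csv(fixture_path("activation"))
  f1 <- fit_hill(tab)
  f2 <- fit_hill(dose_rate_table(tab$lps_ng_ml, tab$rate * 7))
  expect_equal(f2$estimates[["vmax"]], 7 * f1$estimates[["vmax"]],
               tolerance = 1e-6)
  expect_equal(f2$estimates[["c50"]], f1$estimates[["c50"]],
               tolerance = 1e-6)
  expect_equal(f2$estimates[["coef"]], f1$estimates[["coef"]],
               tolerance = 1e-6)
})

test_that("fit_hill enforces its preconditions", {
  expect_error(fit_hill(dose_rate_table(c(1, 2, 3), c(1, 2, 3))),
               "at least 4")
  expect_error(dose_rate_table(c(1, 1, 2, 3), c(1, 2, 3, 4)), "distinct")
  expect_error(dose_rate_table(c(1, -2, 3, 4), c(1, 2, 3, 4)),
               "non-negative")
})

test_that("fit_decay recovers an exact exponential and flags flat series", {
  t <- c(0, 1, 2, 4, 8)
  fit <- fit_decay(data.frame(t_s_h = t, relative_pct = 100 * exp(-0.5 * t)))
  expect_equal(fit$estimates[["rate"]], 0.5, tolerance = 1e-6)

  flat <- fit_decay(data.frame(t_s_h = t, relative_pct = rep(100, 5)))
  expect_equal(flat$estimates[["rate"]], 0)
  expect_true(flat$details$at_lower_bound)
  expect_true(flat$converged)

  expect_error(fit_decay(data.frame(t_s_h = c(0, 1), relative_pct = c(100, 50))),
               "3 distinct")
})

test_that("fit_decay recovers the generating rate under replicate noise,
           averaged over seeds", {
  tgrid <- c(0, 0.1, 0.25, 0.5, 1, 2)
  a_hat <- vapply(1:30, function(s) {
    set.seed(s)
    df <- do.call(rbind, lapply(1:3, function(r)
      data.frame(t_s_h = tgrid,
                 relative_pct = pmax(100 * exp(-4.5 * tgrid) +
                                       rnorm(length(tgrid), 0, 5), 0))))
    fit_decay(df)$estimates[["rate"]]
  }, numeric(1))
  expect_lt(abs(mean(a_hat) - 4.5) / 4.5, 0.10)
})

test_that("build_activation_table assembles per-dose decay fits", {
  t <- c(0, 0.5, 1, 2, 4)
  series <- list(
    "0.2" = data.frame(t_s_h = t, relative_pct = 100 * exp(-1 * t)),
    "2"   = data.frame(t_s_h = t, relative_pct = 100 * exp(-2 * t)))
  tab <- build_activation_table(series)
  expect_s3_class(tab, "dose_rate_table")
  expect_equal(tab$lps_ng_ml, c(0.2, 2))
  expect_equal(tab$rate, c(1, 2), tolerance = 1e-6)
  expect_error(build_activation_table(list()), "empty")
  expect_error(build_activation_table(list(data.frame())), "named")
})

test_that("the optimizer beats a brute-force grid on both packaged
           calibration tables", {
  for (which in c("activation", "tnf")) {
    tab <- read_dose_rate_csv(fixture_path(which))
    fit <- fit_hill(tab)
    grid_best <- hill_grid_best_sse(tab, n = 60)
    expect_lte(fit$sse, grid_best * 1.01 + 1e-12)
  }
})

test_that("joint TNF kinetic refinement recovers perturbed parameters from
           noiseless multi-dose time courses", {
  free <- c("sc50", "immunomodulation_rate", "lps_removal_rate",
            "tnf_degradation_rate")
  doses <- c(5, 0.25, 0.1, 0.05)
  tcs <- setNames(lapply(doses, function(d)
    sim_series(scenario(initial_lps = d), p_true)[, c("time_h", "tnf_pg")]),
    doses)
  p0 <- perturbed_params(p_true, free, 1.5)
  fit <- refine_tnf_kinetics(tcs, p0, step = 0.01)
  expect_true(fit$converged)
  rel <- abs(fit$estimates - unlist(unclass(p_true)[free])) /
    unlist(unclass(p_true)[free])
  expect_lt(max(rel), 0.05)
})

test_that("TNF refinement reports an underdetermined problem instead of
           pretending to converge", {
  fit <- refine_tnf_kinetics(list("5" = data.frame(time_h = 4, tnf_pg = 100)),
                             p_true)
  expect_false(fit$converged)
  expect_identical(fit$details$reason, "underdetermined")
})

test_that("CCL2 optimisation recovers perturbed parameters and scales
           linearly with the data", {
  free <- c("ccl2_synth_resting", "ccl2_synth_inflammatory",
            "ccl2_synth_et", "ccl2_degradation_rate")
  ctrl <- sim_series(preset("fig5_control"), p_true)[, c("time_h", "ccl2_pg")]
  et <- sim_series(preset("fig5_et"), p_true)[, c("time_h", "ccl2_pg")]
  p0 <- perturbed_params(p_true, free, 1.5)
  fit <- fit_ccl2_params(ctrl, et, p0, step = 0.01)
  rel <- abs(fit$estimates - unlist(unclass(p_true)[free])) /
    unlist(unclass(p_true)[free])
  expect_lt(max(rel), 0.05)

  # doubling the observed series doubles the synthesis rates only
  ctrl2 <- transform(ctrl, ccl2_pg = 2 * ccl2_pg)
  et2 <- transform(et, ccl2_pg = 2 * ccl2_pg)
  fit2 <- fit_ccl2_params(ctrl2, et2, p0, step = 0.01)
  ratio <- fit2$estimates / fit$estimates
  expect_equal(unname(ratio[free[1:3]]), rep(2, 3), tolerance = 0.1)
  expect_equal(ratio[["ccl2_degradation_rate"]], 1, tolerance = 0.02)
})

test_that("parameters with no influence on the observed design are flagged
           as weakly identified", {
  # unstimulated culture: the inflammatory and ET pools stay empty early
  # on, so their synthesis rates cannot be identified
  scn <- scenario(initial_lps = 0, horizon = 4)
  obs <- sim_series(scn, p_true, times = c(1, 2, 3, 4))[, c("time_h",
                                                            "ccl2_pg")]
  fit <- fit_ccl2_params(obs, obs, p_true, control_scenario = scn,
                         et_scenario = scn, step = 0.01)
  expect_true(all(c("ccl2_synth_inflammatory", "ccl2_synth_et") %in%
                    fit$details$weakly_identified))
  expect_false("ccl2_synth_resting" %in% fit$details$weakly_identified)
})

test_that("tolerance-index estimation recovers generating indices at the
           boundaries and the sepsis operating point", {
  for (idx in c(0, 68, 100)) {
    ts <- tolerance_scenario(1e6, idx, 5)
    obs <- sim_series(tolerance_index_to_initial_states(ts), p_true)
    fit <- fit_tolerance_index(obs[, c("time_h", "tnf_pg")],
                               obs[, c("time_h", "ccl2_pg")],
                               1e6, p_true, step = 0.01)
    expect_lt(abs(fit$estimates[["tolerance_index"]] - idx), 1)
  }
  # full tolerance leaves nothing to activate: TNF stays at zero
  tr <- simulate_scenario(tolerance_index_to_initial_states(
    tolerance_scenario(1e6, 100, 5)), p_true, step = 0.01)
  expect_true(all(tr$tnf_pg == 0))
})

test_that("all fits are deterministic given data and configuration", {
  tab <- read_dose_rate_csv(fixture_path("activation"))
  expect_identical(fit_hill(tab)$estimates, fit_hill(tab)$estimates)
  t <- c(0, 1, 2, 4)
  df <- data.frame(t_s_h = t, relative_pct = 100 * exp(-1.2 * t))
  expect_identical(fit_decay(df)$estimates, fit_decay(df)$estimates)
})
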