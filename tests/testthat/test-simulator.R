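p_default <- model_parameters()

test_that("unstimulated all-resting culture stays resting with zero TNF", {
  tr <- simulate_scenario(scenario(initial_lps = 0), p_default)
  expect_equal(tr$time_h[1], 0)
  expect_true(all(tr$tnf_pg == 0))
  expect_true(all(tr$resting == 1e6))
  expect_true(all(tr$proinflammatory == 0))
})

test_that("trajectory starts at the scenario's initial state and LPS follows
           first-order decay", {
  scn <- scenario(initial_lps = 5)
  tr <- simulate_scenario(scn, p_default)
  expect_equal(tr$resting[1], 1e6)
  expect_equal(tr$lps_ng_ml[1], 5)
  expect_equal(tr$tnf_pg[1], 0)
  i10 <- which(tr$time_h == 10)
  expect_equal(tr$lps_ng_ml[i10], 5 * exp(-0.0726 * 10), tolerance = 1e-6)
  # whole curve, not just one point
  expect_equal(tr$lps_ng_ml, 5 * exp(-0.0726 * tr$time_h), tolerance = 1e-6)
})

test_that("monocytes are conserved and subset monotonicity holds", {
  for (nm in c("fig5_control", "fig5_et")) {
    tr <- simulate_scenario(preset(nm), p_default)
    tot <- tr$resting + tr$proinflammatory + tr$et
    expect_lt(max(abs(tot - tot[1])), 1e-9 * tot[1])
    expect_true(all(diff(tr$resting) <= 1e-9 * tot[1]))
    expect_true(all(diff(tr$et) >= -1e-9 * tot[1]))
    expect_true(all(diff(tr$lps_ng_ml) <= 0))
  }
})

test_that("long-run CCL2 of an unstimulated culture reaches the
           production/degradation balance", {
  p <- p_default
  tr <- simulate_scenario(scenario(initial_lps = 0, horizon = 200,
                                   output_step = 10), p)
  expect_equal(tail(tr$ccl2_pg, 1),
               1e6 * p$ccl2_synth_resting / p$ccl2_degradation_rate,
               tolerance = 1e-6)
  expect_equal(tail(tr$ccl2_pg, 1), 465, tolerance = 1e-4)
})

test_that("integrator matches the closed-form cascade at constant
           activation rate", {
  p <- update_parameters(p_default, lps_removal_rate = 0)
  # dose at which the activation Hill function equals exactly 1/h
  L <- p$ac50 * (1 / (p$max_activation_rate - 1))^(1 / p$hill_n)
  expect_equal(activation_rate(L, p), 1, tolerance = 1e-12)
  tr <- simulate_scenario(scenario(initial_lps = L, horizon = 4,
                                   output_step = 0.5), p)
  cf <- cascade_closed_form(1e6, 1, p$immunomodulation_rate, tr$time_h)
  for (col in c("resting", "proinflammatory", "et")) {
    i <- tr$time_h > 0
    expect_lt(max(abs(tr[[col]][i] - cf[[col]][i]) /
                    pmax(abs(cf[[col]][i]), 1)), 1e-5)
  }
})

test_that("closed-form cascade honours its boundary behaviour", {
  cf0 <- cascade_closed_form(1e6, 1, 0.1088, 0)
  expect_equal(unlist(cf0), c(resting = 1e6, proinflammatory = 0, et = 0))
  cfL <- cascade_closed_form(1e6, 1, 0.1088, 500)
  expect_equal(cfL$et, 1e6, tolerance = 1e-9)
  expect_error(cascade_closed_form(1e6, 0.5, 0.5, 1), "degenerate")
})

test_that("halving the integration step leaves the trajectory unchanged to
           1e-7 relative", {
  scn <- scenario(initial_lps = 5)
  a <- simulate_scenario(scn, p_default, step = 0.005)
  b <- simulate_scenario(scn, p_default, step = 0.0025)
  for (col in c("resting", "proinflammatory", "et", "lps_ng_ml", "tnf_pg",
                "ccl2_pg"))
    expect_lt(max(abs(a[[col]] - b[[col]]) / pmax(abs(b[[col]]), 1e-3)),
              1e-7)
})

test_that("a step that does not divide the TNF delay is rejected", {
  expect_error(simulate_scenario(scenario(initial_lps = 5), p_default,
                                 step = 0.3), "divide")
  # delay-free model accepts any step
  p0 <- update_parameters(p_default, tnf_delay_td = 0)
  expect_silent(simulate_scenario(scenario(initial_lps = 5, horizon = 2),
                                  p0, step = 0.3))
})

test_that("simulator agrees with an independent DDE solver", {
  skip_if_not_installed("deSolve")
  p <- p_default
  rhs <- function(t, y, parms) {
    pd <- if (t <= p$tnf_delay_td) 0 else
      deSolve::lagvalue(t - p$tnf_delay_td, 2)
    act <- activation_rate(max(y[4], 0), p)
    syn <- tnf_synthesis_rate(max(y[4], 0), p)
    list(c(-y[1] * act,
           y[1] * act - y[2] * p$immunomodulation_rate,
           y[2] * p$immunomodulation_rate,
           -y[4] * p$lps_removal_rate,
           pd * syn - y[5] * p$tnf_degradation_rate,
           y[1] * p$ccl2_synth_resting + y[2] * p$ccl2_synth_inflammatory +
             y[3] * p$ccl2_synth_et - y[6] * p$ccl2_degradation_rate))
  }
  times <- seq(0, 24, by = 1)
  ref <- deSolve::dede(c(1e6, 0, 0, 5, 0, 0), times, rhs, NULL,
                       control = list(mxhist = 1e5))
  tr <- simulate_scenario(scenario(initial_lps = 5, output_step = 1),
                          p_default)
  expect_equal(tr$tnf_pg, ref[, 6], tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(tr$proinflammatory, ref[, 3], tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(tr$ccl2_pg, ref[, 7], tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("trajectories expose flows consistent with the states", {
  tr <- simulate_scenario(scenario(initial_lps = 5), p_default)
  expect_equal(tr$flow_activation,
               tr$resting * activation_rate(tr$lps_ng_ml, p_default))
  expect_equal(tr$flow_ccl2_degradation,
               tr$ccl2_pg * p_default$ccl2_degradation_rate)
  expect_true(all(as.matrix(tr[grep("^flow_", names(tr))]) >= 0))
})
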