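# Independent oracles and shared fixtures for the suite.

PARAMS <- c("max_activation_rate", "ac50", "hill_n", "immunomodulation_rate",
            "lps_removal_rate", "max_tnf_synthesis_rate", "sc50", "hill_m",
            "tnf_delay_td", "tnf_degradation_rate", "ccl2_synth_resting",
            "ccl2_synth_inflammatory", "ccl2_synth_et",
            "ccl2_degradation_rate")

# direct high-precision evaluation of the saturating Hill form, written
# independently of the package's implementation
oracle_hill <- function(L, vmax, c50, k) {
  if (L == 0) return(0)
  vmax / (1 + exp(k * (log(c50) - log(L))))
}

# brute-force best SSE of a Hill fit over an n^3 log-spaced parameter grid
hill_grid_best_sse <- function(tab, n = 60,
                               vmax_range = c(max(tab$rate) / 10,
                                              max(tab$rate) * 10),
                               c50_range = c(1e-4, 10),
                               coef_range = c(0.3, 5)) {
  vg <- exp(seq(log(vmax_range[1]), log(vmax_range[2]), length.out = n))
  cg <- exp(seq(log(c50_range[1]), log(c50_range[2]), length.out = n))
  kg <- exp(seq(log(coef_range[1]), log(coef_range[2]), length.out = n))
  # SSE(v, c, k) = sum_d r_d^2 - 2 v B(c, k) + v^2 C(c, k)
  B <- matrix(0, n, n)
  C <- matrix(0, n, n)
  for (d in seq_len(nrow(tab))) {
    L <- tab$lps_ng_ml[d]
    if (L == 0) next  # Hill form is identically 0 at zero dose
    A <- outer(cg, kg, function(ci, ki) L^ki / (ci^ki + L^ki))
    B <- B + tab$rate[d] * A
    C <- C + A^2
  }
  r2 <- sum(tab$rate^2)
  best <- Inf
  for (i in seq_len(n))
    best <- min(best, r2 - 2 * vg[i] * B + vg[i]^2 * C)
  best
}

# noiseless cytokine time courses on an experimental grid
sim_series <- function(scn, p, times = c(1, 2, 4, 8, 16, 24), step = 0.01) {
  tr <- simulate_scenario(scn, p, step = step, times = times)
  data.frame(time_h = times, tnf_pg = tr$tnf_pg, ccl2_pg = tr$ccl2_pg)
}

perturbed_params <- function(p, free, factor = 1.5) {
  for (f in free) p[[f]] <- p[[f]] * factor
  do.call(model_parameters, unclass(p)[PARAMS])
}
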