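#' Define a simulation scenario
#'
#' A scenario fixes the initial composition of the culture (counts of
#' resting, proinflammatory and ET monocytes), the initial LPS dose, initial
#' cytokine masses, the horizon and the output grid. The default horizon and
#' sampling match a 24 h culture experiment.
#'
#' @param initial_resting,initial_proinflammatory,initial_et Initial monocyte
#'   counts per subset.
#' @param initial_lps Initial LPS concentration, ng/ml.
#' @param initial_tnf,initial_ccl2 Initial cytokine masses, pg.
#' @param horizon Simulation horizon, hours.
#' @param output_step Output sampling interval, hours.
#' @return An object of class `scenario`.
#' @export
scenario <- function(initial_resting = 1e6, initial_proinflammatory = 0,
                     initial_et = 0, initial_lps = 0, initial_tnf = 0,
                     initial_ccl2 = 0, horizon = 24, output_step = 0.1) {
  s <- list(initial_resting = initial_resting,
            initial_proinflammatory = initial_proinflammatory,
            initial_et = initial_et, initial_lps = initial_lps,
            initial_tnf = initial_tnf, initial_ccl2 = initial_ccl2,
            horizon = horizon, output_step = output_step)
  for (nm in names(s))
    if (!is.numeric(s[[nm]]) || length(s[[nm]]) != 1L || !is.finite(s[[nm]]))
      stop("scenario field '", nm, "' must be a single finite number",
           call. = FALSE)
  if (any(unlist(s[1:6]) < 0))
    stop("initial stocks must be non-negative", call. = FALSE)
  if (s$horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  if (s$output_step <= 0 || s$output_step > s$horizon)
    stop("output_step must be in (0, horizon]", call. = FALSE)
  structure(s, class = "scenario")
}

initial_state <- function(scn) {
  c(resting = scn$initial_resting,
    proinflammatory = scn$initial_proinflammatory,
    et = scn$initial_et, lps = scn$initial_lps,
    tnf = scn$initial_tnf, ccl2 = scn$initial_ccl2)
}

#' Simulate the monocyte endotoxin-tolerance model
#'
#' Integrates the six balance equations (three monocyte subsets, LPS, TNF,
#' CCL2) over a scenario with a fixed-step classical Runge-Kutta scheme and
#' the method of steps for the TNF production delay. The pre-history of the
#' proinflammatory stock is constant and equal to its initial value (the
#' culture is at its initial composition before the stimulus). The step must
#' divide the delay exactly so delayed values are read from stored nodes;
#' off-grid output times are filled by cubic Hermite interpolation.
#'
#' @param scn A [scenario()].
#' @param p A [model_parameters()] object.
#' @param step Integration step, hours. Must divide `tnf_delay_td`.
#' @param times Optional explicit output times (hours); defaults to the
#'   scenario's regular grid `seq(0, horizon, by = output_step)`.
#' @return A data frame of class `monotol_trajectory` with columns `time_h`,
#'   the six stocks (`resting`, `proinflammatory`, `et`, `lps_ng_ml`,
#'   `tnf_pg`, `ccl2_pg`) and the seven evaluated flows (`flow_*` columns).
#'   The scenario, parameters and step are attached as attributes.
#' @examples
#' tr <- simulate_scenario(scenario(initial_lps = 5))
#' max(tr$tnf_pg)
#' @export
simulate_scenario <- function(scn, p = model_parameters(), step = 0.005,
                              times = NULL) {
  stopifnot(inherits(scn, "scenario"), inherits(p, "model_parameters"))
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (p$tnf_delay_td > 0) {
    k <- round(p$tnf_delay_td / step)
    if (k < 1 || abs(k * step - p$tnf_delay_td) > 1e-9 * max(1, p$tnf_delay_td))
      stop("integration step (", step, " h) must divide the TNF delay (",
           p$tnf_delay_td, " h) exactly", call. = FALSE)
  }
  if (is.null(times))
    times <- seq(0, scn$horizon, by = scn$output_step)
  times <- sort(unique(as.numeric(times)))
  if (any(times < 0) || any(times > scn$horizon + 1e-9))
    stop("output times must lie in [0, horizon]", call. = FALSE)

  y0 <- initial_state(scn)
  res <- .simulate_core(unname(y0), unname(param_vector(p)), scn$horizon,
                        step, times)
  st <- res$states
  total0 <- sum(y0[1:3])
  if (min(res$min_state) < -1e-9 * max(total0, 1))
    stop("integration produced a negative state beyond tolerance; ",
         "min = ", min(res$min_state), call. = FALSE)

  out <- data.frame(time_h = st[, 1], resting = st[, 2],
                    proinflammatory = st[, 3], et = st[, 4],
                    lps_ng_ml = st[, 5], tnf_pg = st[, 6], ccl2_pg = st[, 7])
  pdel <- st[, 8]
  fl <- cbind(
    flow_activation       = out$resting * activation_rate(pmax(out$lps_ng_ml, 0), p),
    flow_immunomodulation = out$proinflammatory * p$immunomodulation_rate,
    flow_lps_removal      = out$lps_ng_ml * p$lps_removal_rate,
    flow_tnf_production   = pdel * tnf_synthesis_rate(pmax(out$lps_ng_ml, 0), p),
    flow_tnf_degradation  = out$tnf_pg * p$tnf_degradation_rate,
    flow_ccl2_production  = out$resting * p$ccl2_synth_resting +
                            out$proinflammatory * p$ccl2_synth_inflammatory +
                            out$et * p$ccl2_synth_et,
    flow_ccl2_degradation = out$ccl2_pg * p$ccl2_degradation_rate)
  out <- cbind(out, as.data.frame(fl))
  structure(out, class = c("monotol_trajectory", "data.frame"),
            scenario = scn, parameters = p, step = step)
}

#' Closed-form monocyte cascade under a constant activation rate
#'
#' Analytic solution of the resting -> proinflammatory -> ET cascade when the
#' activation rate is a constant `a` (e.g. LPS held constant with zero
#' removal) and the immunomodulation rate is `i`. Serves as an independent
#' oracle for the integrator.
#'
#' @param r0 Initial resting monocyte count.
#' @param a Constant activation rate, per hour; must differ from `i`.
#' @param i Immunomodulation rate, per hour.
#' @param t Time(s), hours.
#' @return Data frame with columns `resting`, `proinflammatory`, `et`.
#' @export
cascade_closed_form <- function(r0, a, i, t) {
  if (a <= 0 || i <= 0) stop("a and i must be > 0", call. = FALSE)
  if (a == i)
    stop("degenerate case a == i; perturb one of the rates", call. = FALSE)
  resting <- r0 * exp(-a * t)
  pro <- a * r0 * (exp(-a * t) - exp(-i * t)) / (i - a)
  data.frame(resting = resting, proinflammatory = pro,
             et = r0 - resting - pro)
}
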