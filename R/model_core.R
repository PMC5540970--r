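#' Hill-modulated activation rate
#'
#' Instantaneous activation rate of resting monocytes at a given LPS
#' concentration: `max_activation_rate * lps^n / (ac50^n + lps^n)`. Zero at
#' zero LPS, strictly increasing, bounded by `max_activation_rate`.
#'
#' @param lps LPS concentration(s), ng/ml; must be non-negative.
#' @param p A [model_parameters()] object.
#' @return Activation rate(s), per hour.
#' @export
activation_rate <- function(lps, p = model_parameters()) {
  stopifnot(inherits(p, "model_parameters"))
  hill_response(lps, p$max_activation_rate, p$ac50, p$hill_n)
}

#' Hill-modulated TNF synthesis rate
#'
#' Per-monocyte TNF synthesis rate at a given LPS concentration:
#' `max_tnf_synthesis_rate * lps^m / (sc50^m + lps^m)`.
#'
#' @inheritParams activation_rate
#' @return TNF synthesis rate(s), pg per hour per monocyte.
#' @export
tnf_synthesis_rate <- function(lps, p = model_parameters()) {
  stopifnot(inherits(p, "model_parameters"))
  hill_response(lps, p$max_tnf_synthesis_rate, p$sc50, p$hill_m)
}

#' Saturating Hill dose-response
#'
#' `vmax * lps^coef / (c50^coef + lps^coef)`, the functional form shared by
#' both model auxiliaries; exactly 0 at `lps = 0` for any positive exponent.
#'
#' @param lps Dose(s), ng/ml; non-negative.
#' @param vmax Plateau value.
#' @param c50 Half-saturation dose, ng/ml.
#' @param coef Hill exponent (> 0).
#' @return Response value(s), same units as `vmax`.
#' @export
hill_response <- function(lps, vmax, c50, coef) {
  if (!is.numeric(lps) || any(!is.finite(lps)))
    stop("lps must be finite and numeric", call. = FALSE)
  if (any(lps < 0))
    stop("lps must be non-negative", call. = FALSE)
  # 0^coef is 0 for coef > 0, so lps = 0 maps to exactly 0
  ifelse(lps == 0, 0, vmax * lps^coef / (c50^coef + lps^coef))
}

#' Instantaneous model flows
#'
#' Evaluates the seven flows of the model at one state: activation,
#' immunomodulation, LPS removal, TNF production (from the delayed
#' proinflammatory stock but the current LPS concentration), TNF degradation,
#' CCL2 production (summed over the three subsets), and CCL2 degradation.
#'
#' @param state Named numeric vector or list with elements `resting`,
#'   `proinflammatory`, `et`, `lps`, `tnf`, `ccl2`.
#' @param proinflammatory_delayed Proinflammatory stock `tnf_delay_td` hours
#'   earlier; defaults to the current stock (no-delay evaluation).
#' @param p A [model_parameters()] object.
#' @return Named numeric vector of the seven flows. Monocyte flows are in
#'   monocytes/h, LPS removal in ng/ml/h, cytokine flows in pg/h.
#' @export
model_flows <- function(state, proinflammatory_delayed = NULL,
                        p = model_parameters()) {
  s <- as.list(state)
  need <- c("resting", "proinflammatory", "et", "lps", "tnf", "ccl2")
  if (!all(need %in% names(s)))
    stop("state must contain: ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(proinflammatory_delayed))
    proinflammatory_delayed <- s$proinflammatory
  vals <- unlist(s[need])
  if (any(vals < 0) || proinflammatory_delayed < 0)
    stop("state must be non-negative", call. = FALSE)
  c(activation        = s$resting * activation_rate(s$lps, p),
    immunomodulation  = s$proinflammatory * p$immunomodulation_rate,
    lps_removal       = s$lps * p$lps_removal_rate,
    tnf_production    = proinflammatory_delayed * tnf_synthesis_rate(s$lps, p),
    tnf_degradation   = s$tnf * p$tnf_degradation_rate,
    ccl2_production   = s$resting * p$ccl2_synth_resting +
                        s$proinflammatory * p$ccl2_synth_inflammatory +
                        s$et * p$ccl2_synth_et,
    ccl2_degradation  = s$ccl2 * p$ccl2_degradation_rate)
}
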