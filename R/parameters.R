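# Canonical parameter order shared with the C++ integrator.
PARAM_NAMES <- c(
  "max_activation_rate", "ac50", "hill_n",
  "immunomodulation_rate", "lps_removal_rate",
  "max_tnf_synthesis_rate", "sc50", "hill_m",
  "tnf_delay_td", "tnf_degradation_rate",
  "ccl2_synth_resting", "ccl2_synth_inflammatory", "ccl2_synth_et",
  "ccl2_degradation_rate"
)

#' Model parameters for the monocyte endotoxin-tolerance model
#'
#' Builds the 14-parameter set governing the six-stock model: activation of
#' resting monocytes by LPS (Hill-modulated), immunomodulation into the
#' endotoxin-tolerant (ET) state, first-order LPS removal, delayed
#' Hill-modulated TNF synthesis, and subset-specific CCL2 synthesis, with
#' first-order degradation of both cytokines. Defaults are the calibrated
#' reference values for human monocytes.
#'
#' @param max_activation_rate Maximum monocyte activation rate (per hour).
#' @param ac50 LPS concentration giving half-maximal activation (ng/ml).
#' @param hill_n Hill coefficient of the activation dose-response.
#' @param immunomodulation_rate First-order rate of transition from the
#'   proinflammatory to the ET state (per hour); LPS-independent.
#' @param lps_removal_rate First-order LPS clearance rate (per hour).
#' @param max_tnf_synthesis_rate Maximum TNF synthesis rate
#'   (pg per hour per monocyte).
#' @param sc50 LPS concentration giving half-maximal TNF synthesis (ng/ml).
#' @param hill_m Hill coefficient of the TNF-synthesis dose-response.
#' @param tnf_delay_td Delay between monocyte activation and TNF output
#'   (hours); models the signalling cascade (NF-kB translocation) lag.
#' @param tnf_degradation_rate First-order TNF decay rate (per hour).
#' @param ccl2_synth_resting,ccl2_synth_inflammatory,ccl2_synth_et CCL2
#'   synthesis rates of the three monocyte subsets (pg per hour per monocyte).
#' @param ccl2_degradation_rate First-order CCL2 decay rate (per hour).
#'
#' @return An object of class `model_parameters` (a named list).
#' @examples
#' p <- model_parameters()
#' activation_rate(5, p)
#' @export
model_parameters <- function(max_activation_rate = 4.4990,
                             ac50 = 0.1889,
                             hill_n = 1.4825,
                             immunomodulation_rate = 0.1088,
                             lps_removal_rate = 0.0726,
                             max_tnf_synthesis_rate = 0.0071,
                             sc50 = 0.0890,
                             hill_m = 1.7670,
                             tnf_delay_td = 1,
                             tnf_degradation_rate = 0.1362,
                             ccl2_synth_resting = 0.1315e-3,
                             ccl2_synth_inflammatory = 0.1315e-3,
                             ccl2_synth_et = 0.4633e-2,
                             ccl2_degradation_rate = 0.2828) {
  p <- mget(PARAM_NAMES)
  validate_parameters(p)
  structure(p, class = "model_parameters")
}

validate_parameters <- function(p) {
  for (nm in PARAM_NAMES) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  if (p$hill_n <= 0) stop("parameter 'hill_n' must be > 0", call. = FALSE)
  if (p$hill_m <= 0) stop("parameter 'hill_m' must be > 0", call. = FALSE)
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named parameters replaced; the result is
#' re-validated.
#'
#' @param p A `model_parameters` object.
#' @param ... Named parameter replacements, e.g. `sc50 = 0.14`.
#' @return A `model_parameters` object.
#' @export
update_parameters <- function(p, ...) {
  stopifnot(inherits(p, "model_parameters"))
  repl <- list(...)
  unknown <- setdiff(names(repl), PARAM_NAMES)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p[names(repl)] <- repl
  validate_parameters(p)
  structure(p[PARAM_NAMES], class = "model_parameters")
}

# numeric vector in the canonical order expected by the C++ core
param_vector <- function(p) {
  stopifnot(inherits(p, "model_parameters"))
  unlist(p[PARAM_NAMES], use.names = TRUE)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Monocyte endotoxin-tolerance model parameters:\n")
  v <- param_vector(x)
  for (nm in names(v))
    cat(sprintf("  %-26s %s\n", nm, formatC(v[[nm]], digits = 10,
                                            format = "g")))
  invisible(x)
}
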