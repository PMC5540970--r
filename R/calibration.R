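#' Dose-rate calibration table
#'
#' Pairs of LPS concentration and an empirically estimated rate (activation
#' rate in /h, or TNF synthesis rate in pg/h/monocyte), the input of
#' [fit_hill()].
#'
#' @param lps LPS concentrations, ng/ml; distinct and non-negative.
#' @param rate Estimated rates; non-negative.
#' @return A data frame of class `dose_rate_table` with columns `lps_ng_ml`
#'   and `rate`.
#' @export
dose_rate_table <- function(lps, rate) {
  if (length(lps) != length(rate) || !length(lps))
    stop("lps and rate must be non-empty and of equal length", call. = FALSE)
  if (anyDuplicated(lps)) stop("lps values must be distinct", call. = FALSE)
  if (any(lps < 0) || any(rate < 0))
    stop("lps and rate must be non-negative", call. = FALSE)
  structure(data.frame(lps_ng_ml = as.numeric(lps), rate = as.numeric(rate)),
            class = c("dose_rate_table", "data.frame"))
}

fit_result <- function(estimates, sse, n_points, converged, details = list()) {
  structure(list(estimates = estimates, sse = sse, n_points = n_points,
                 converged = converged, details = details),
            class = "monotol_fit")
}

#' @export
print.monotol_fit <- function(x, ...) {
  cat("Fit (", if (x$converged) "converged" else "NOT converged",
      ", n = ", x$n_points, ", SSE = ",
      formatC(x$sse, digits = 6, format = "g"), "):\n", sep = "")
  for (nm in names(x$estimates))
    cat(sprintf("  %-26s %s\n", nm,
                formatC(x$estimates[[nm]], digits = 10, format = "g")))
  invisible(x)
}

# default multistart grid on the half-saturation constant
DEFAULT_C50_STARTS <- 10^seq(-4, 1, length.out = 12)

#' Fit a Hill dose-response curve
#'
#' Estimates `(vmax, c50, coef)` of the saturating Hill function
#' `rate = vmax * L^coef / (c50^coef + L^coef)` by unweighted nonlinear least
#' squares on the linear rate and dose scales, using Levenberg-Marquardt
#' refinement from a log-spaced multistart grid on `c50`. The best start by
#' SSE wins; the procedure is deterministic given data, bounds and starts.
#'
#' @param table A [dose_rate_table()] (or data frame with columns
#'   `lps_ng_ml`, `rate`); at least 4 rows for the 3-parameter fit.
#' @param bounds Named list of length-2 lower/upper bounds for `vmax`,
#'   `c50` and `coef`.
#' @param c50_starts Multistart values for the half-saturation constant.
#' @return A `monotol_fit` with estimates `vmax`, `c50`, `coef`.
#' @examples
#' tab <- dose_rate_table(c(5, 1, 0.2, 0.04),
#'                        hill_response(c(5, 1, 0.2, 0.04), 2, 0.2, 1.5))
#' fit_hill(tab)$estimates
#' @export
fit_hill <- function(table,
                     bounds = list(vmax = c(1e-9, 1e4),
                                   c50 = c(1e-6, 1e3),
                                   coef = c(0.1, 10)),
                     c50_starts = DEFAULT_C50_STARTS) {
  table <- as_dose_rate_table(table)
  if (nrow(table) < 4)
    stop("at least 4 dose-rate rows are needed for a 3-parameter Hill fit",
         call. = FALSE)
  if (any(unlist(bounds) <= 0))
    stop("bounds must be positive", call. = FALSE)
  lps <- table$lps_ng_ml
  rate <- table$rate
  sse_of <- function(v, c50, k) sum((rate - hill_response(lps, v, c50, k))^2)
  lower <- c(bounds$vmax[1], bounds$c50[1], bounds$coef[1])
  upper <- c(bounds$vmax[2], bounds$c50[2], bounds$coef[2])
  v_start <- min(max(1.05 * max(rate), lower[1]), upper[1])

  best <- NULL
  for (c0 in c50_starts) {
    c0 <- min(max(c0, lower[2]), upper[2])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rate ~ vmax * lps^coef / (c50^coef + lps^coef),
        data = data.frame(lps = lps, rate = rate),
        start = list(vmax = v_start, c50 = c0, coef = 1.5),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    est <- stats::coef(fit)
    s <- sse_of(est[["vmax"]], est[["c50"]], est[["coef"]])
    if (is.null(best) || s < best$sse)
      best <- list(estimates = c(vmax = est[["vmax"]], c50 = est[["c50"]],
                                 coef = est[["coef"]]), sse = s)
  }
  if (is.null(best))
    stop("Hill fit failed to converge from any start (",
         length(c50_starts), " starts tried)", call. = FALSE)
  fit_result(best$estimates, best$sse, nrow(table), TRUE,
             details = list(bounds = bounds, c50_starts = c50_starts))
}

as_dose_rate_table <- function(table) {
  if (inherits(table, "dose_rate_table")) return(table)
  if (!all(c("lps_ng_ml", "rate") %in% names(table)))
    stop("table must have columns lps_ng_ml and rate", call. = FALSE)
  dose_rate_table(table$lps_ng_ml, table$rate)
}

#' Fit a one-phase decay to a two-stimulus readout
#'
#' Fits `relative_pct(t_s) = 100 * exp(-a * t_s)` by unweighted least squares
#' over a bounded 1-D search on `a`. The fraction-of-control TNF response
#' after a second LPS challenge estimates the fraction of monocytes still
#' resting after a first stimulus of duration `t_s`, so `a` estimates the
#' activation rate at the first-stimulus dose. No plateau term is used:
#' resting-monocyte depletion at constant dose is a pure exponential.
#'
#' @param series Data frame with columns `t_s_h` (duration of the first
#'   stimulus, hours) and `relative_pct` (% of the unprimed control
#'   response); at least 3 distinct `t_s_h` values. Replicate rows per
#'   `t_s_h` are allowed.
#' @param upper Upper search bound for the rate, per hour.
#' @return A `monotol_fit` with estimate `rate`. A best fit at the zero
#'   lower bound (non-decaying series) sets `details$at_lower_bound` and is
#'   flagged, not an error.
#' @export
fit_decay <- function(series, upper = 50) {
  if (!all(c("t_s_h", "relative_pct") %in% names(series)))
    stop("series must have columns t_s_h and relative_pct", call. = FALSE)
  if (length(unique(series$t_s_h)) < 3)
    stop("need at least 3 distinct t_s_h values", call. = FALSE)
  if (any(series$t_s_h < 0)) stop("t_s_h must be >= 0", call. = FALSE)
  t <- series$t_s_h
  y <- series$relative_pct
  sse <- function(a) sum((y - 100 * exp(-a * t))^2)
  # coarse scan guards against local minima, then golden-section refinement
  grid <- seq(0, upper, length.out = 501)
  g <- vapply(grid, sse, numeric(1))
  i <- which.min(g)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-12)
  a <- opt$minimum
  s0 <- sse(0)
  if (s0 <= opt$objective) { a <- 0; opt$objective <- s0 }
  fit_result(c(rate = a), opt$objective, nrow(series), TRUE,
             details = list(at_lower_bound = a == 0, upper = upper))
}

#' Assemble a dose to activation-rate table from decay series
#'
#' Applies [fit_decay()] to the two-stimulus readout series of each
#' first-stimulus dose and assembles the resulting `(dose, rate)` pairs into
#' a [dose_rate_table()] ready for [fit_hill()].
#'
#' @param series_by_dose Named list mapping the first-stimulus LPS dose
#'   (ng/ml, as the element name) to a decay series data frame
#'   (see [fit_decay()]).
#' @return A `dose_rate_table`.
#' @export
build_activation_table <- function(series_by_dose) {
  if (!length(series_by_dose))
    stop("series_by_dose must not be empty", call. = FALSE)
  doses <- suppressWarnings(as.numeric(names(series_by_dose)))
  if (is.null(names(series_by_dose)) || any(is.na(doses)))
    stop("series_by_dose must be named by numeric LPS dose", call. = FALSE)
  rates <- vapply(seq_along(series_by_dose), function(j) {
    f <- tryCatch(fit_decay(series_by_dose[[j]]), error = function(e)
      stop("decay fit failed for dose ", doses[j], " ng/ml: ",
           conditionMessage(e), call. = FALSE))
    f$estimates[["rate"]]
  }, numeric(1))
  dose_rate_table(doses, rates)
}

# shared engine for simulate-and-compare least squares on log-parameters
sim_lsq <- function(objective, p0, free, multistart = list(), step = 0.005,
                    n_points, bound_factor = 100) {
  x0 <- log(unlist(p0[free]))
  lower <- x0 - log(bound_factor)
  upper <- x0 + log(bound_factor)
  starts <- list(x0)
  for (ms in multistart) {
    x <- x0
    x[names(ms)] <- x[names(ms)] + log(unlist(ms))
    starts <- c(starts, list(pmin(pmax(x, lower), upper)))
  }
  best <- NULL
  for (x in starts) {
    r <- tryCatch(
      stats::optim(x, objective, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(r)) next
    if (is.null(best) || r$value < best$value) best <- r
  }
  if (is.null(best))
    stop("optimization failed from every start", call. = FALSE)
  est <- exp(best$par)
  names(est) <- free
  fit_result(est, best$value, n_points, best$convergence == 0,
             details = list(start = unlist(p0[free]),
                            bound_factor = bound_factor))
}

#' Jointly refine TNF kinetic parameters against time courses
#'
#' Re-estimates `sc50`, the immunomodulation rate, the LPS removal rate and
#' the TNF degradation rate by minimizing the total (unweighted) squared
#' error between simulated TNF and all supplied dose time courses at once,
#' with bounded quasi-Newton refinement on log-parameters from `p0` and a
#' coarse multistart on `sc50`.
#'
#' @param timecourses Named list mapping LPS dose (ng/ml, as the element
#'   name) to a data frame with columns `time_h` and `tnf_pg`.
#' @param p0 Starting [model_parameters()]; non-free parameters stay fixed.
#' @param free Character vector of parameters to re-estimate.
#' @param initial_resting Monocyte count of the underlying cultures.
#' @param step Integration step for the embedded simulations, hours.
#' @return A `monotol_fit`. With fewer data points than free parameters the
#'   problem is underdetermined: the fit returns unconverged with the
#'   starting estimates.
#' @export
refine_tnf_kinetics <- function(timecourses, p0 = model_parameters(),
                                free = c("sc50", "immunomodulation_rate",
                                         "lps_removal_rate",
                                         "tnf_degradation_rate"),
                                initial_resting = 1e6, step = 0.005) {
  stopifnot(inherits(p0, "model_parameters"))
  doses <- suppressWarnings(as.numeric(names(timecourses)))
  if (!length(timecourses) || any(is.na(doses)))
    stop("timecourses must be named by numeric LPS dose", call. = FALSE)
  for (tc in timecourses)
    if (!all(c("time_h", "tnf_pg") %in% names(tc)))
      stop("each time course needs columns time_h and tnf_pg", call. = FALSE)
  n_points <- sum(vapply(timecourses, nrow, integer(1)))
  if (n_points < length(free))
    return(fit_result(unlist(p0[free]), NA_real_, n_points, FALSE,
                      details = list(reason = "underdetermined")))

  objective <- function(x) {
    p <- p0
    p[free] <- as.list(exp(x))
    p <- tryCatch(structure(validate_parameters(p), class = "model_parameters"),
                  error = function(e) NULL)
    if (is.null(p)) return(1e12)
    tot <- 0
    for (j in seq_along(timecourses)) {
      tc <- timecourses[[j]]
      scn <- scenario(initial_resting = initial_resting,
                      initial_lps = doses[j], horizon = max(tc$time_h),
                      output_step = max(tc$time_h))
      tr <- simulate_scenario(scn, p, step = step, times = tc$time_h)
      tot <- tot + sum((tr$tnf_pg - tc$tnf_pg)^2)
    }
    tot
  }
  sim_lsq(objective, p0, free,
          multistart = list(list(sc50 = 0.3), list(sc50 = 3)),
          step = step, n_points = n_points)
}

#' Optimize the CCL2 synthesis and degradation parameters
#'
#' Estimates the three subset-specific CCL2 synthesis rates and the CCL2
#' degradation rate by minimizing the total squared error between simulated
#' CCL2 and observed control and endotoxin-tolerance time courses
#' simultaneously (both cultures challenged with the same LPS dose).
#'
#' @param control,et Data frames with columns `time_h` and `ccl2_pg`: the
#'   all-resting control culture and the ET culture (initial split
#'   0 / 75,000 / 925,000 by default).
#' @param p0 Starting [model_parameters()].
#' @param control_scenario,et_scenario Scenarios for the two cultures;
#'   horizons are adapted to the data.
#' @param lps Challenge dose, ng/ml (used only for the default scenarios).
#' @param step Integration step, hours.
#' @return A `monotol_fit`. `details$weakly_identified` names parameters
#'   whose doubling changes the optimal SSE by less than 1e-6 of the data
#'   scale (e.g. the inflammatory vs ET synthesis rates when both series
#'   coincide).
#' @export
fit_ccl2_params <- function(control, et, p0 = model_parameters(),
                            control_scenario = NULL, et_scenario = NULL,
                            lps = 5, step = 0.005) {
  stopifnot(inherits(p0, "model_parameters"))
  for (tc in list(control, et))
    if (!all(c("time_h", "ccl2_pg") %in% names(tc)))
      stop("series need columns time_h and ccl2_pg", call. = FALSE)
  free <- c("ccl2_synth_resting", "ccl2_synth_inflammatory",
            "ccl2_synth_et", "ccl2_degradation_rate")
  if (is.null(control_scenario))
    control_scenario <- scenario(initial_resting = 1e6, initial_lps = lps,
                                 horizon = max(control$time_h))
  if (is.null(et_scenario))
    et_scenario <- scenario(initial_resting = 0,
                            initial_proinflammatory = 75000,
                            initial_et = 925000, initial_lps = lps,
                            horizon = max(et$time_h))
  data <- list(list(scn = control_scenario, tc = control),
               list(scn = et_scenario, tc = et))
  n_points <- nrow(control) + nrow(et)
  if (n_points < length(free))
    return(fit_result(unlist(p0[free]), NA_real_, n_points, FALSE,
                      details = list(reason = "underdetermined")))
  objective <- function(x) {
    p <- p0
    p[free] <- as.list(exp(x))
    tot <- 0
    for (d in data) {
      tr <- simulate_scenario(d$scn, structure(p, class = "model_parameters"),
                              step = step, times = d$tc$time_h)
      tot <- tot + sum((tr$ccl2_pg - d$tc$ccl2_pg)^2)
    }
    tot
  }
  fit <- sim_lsq(objective, p0, free, step = step, n_points = n_points)
  # sensitivity screen: a parameter whose doubling barely moves the SSE is
  # not identified by these data
  scale <- sum(control$ccl2_pg^2) + sum(et$ccl2_pg^2)
  x_hat <- log(fit$estimates)
  weak <- character(0)
  for (j in seq_along(free)) {
    x <- x_hat
    x[j] <- x[j] + log(2)
    if (abs(objective(x) - fit$sse) < 1e-6 * max(scale, 1))
      weak <- c(weak, free[j])
  }
  fit$details$weakly_identified <- weak
  fit
}

#' Estimate the tolerance index of a monocyte culture
#'
#' The tolerance index (0-100) is the percentage of the initial monocyte
#' population in the ET state; resting monocytes make up the remainder and
#' the proinflammatory pool starts empty. Given observed TNF and CCL2 time
#' courses after an LPS challenge, the index is estimated by minimizing the
#' sum of the per-cytokine standardized squared errors (each cytokine's SSE
#' divided by the variance of its observed series, so neither magnitude
#' dominates) over a bounded 1-D search: an integer grid scan over 0 to 100
#' followed by golden-section refinement in the best bracket.
#'
#' @param tnf_series,ccl2_series Data frames with columns `time_h` and
#'   `tnf_pg` / `ccl2_pg` respectively.
#' @param total Total initial monocyte count of the culture.
#' @param p A [model_parameters()] object.
#' @param lps Challenge dose, ng/ml.
#' @param step Integration step, hours.
#' @return A `monotol_fit` with estimate `tolerance_index`.
#' @export
fit_tolerance_index <- function(tnf_series, ccl2_series, total = 1e6,
                                p = model_parameters(), lps = 5,
                                step = 0.005) {
  stopifnot(inherits(p, "model_parameters"))
  if (!all(c("time_h", "tnf_pg") %in% names(tnf_series)) ||
      !all(c("time_h", "ccl2_pg") %in% names(ccl2_series)))
    stop("need tnf_series(time_h, tnf_pg) and ccl2_series(time_h, ccl2_pg)",
         call. = FALSE)
  if (!nrow(tnf_series) || !nrow(ccl2_series))
    stop("observed series must be non-empty", call. = FALSE)
  if (total <= 0) stop("total must be > 0", call. = FALSE)
  w_tnf <- stats::var(tnf_series$tnf_pg)
  if (!isTRUE(w_tnf > 0)) w_tnf <- max(mean(tnf_series$tnf_pg)^2, 1)
  w_ccl2 <- stats::var(ccl2_series$ccl2_pg)
  if (!isTRUE(w_ccl2 > 0)) w_ccl2 <- max(mean(ccl2_series$ccl2_pg)^2, 1)
  horizon <- max(tnf_series$time_h, ccl2_series$time_h)
  times <- sort(unique(c(tnf_series$time_h, ccl2_series$time_h)))

  objective <- function(idx) {
    ts <- tolerance_scenario(total, idx, lps, horizon = horizon)
    tr <- simulate_scenario(tolerance_index_to_initial_states(ts), p,
                            step = step, times = times)
    sim_tnf <- tr$tnf_pg[match(tnf_series$time_h, tr$time_h)]
    sim_ccl2 <- tr$ccl2_pg[match(ccl2_series$time_h, tr$time_h)]
    sum((sim_tnf - tnf_series$tnf_pg)^2) / w_tnf +
      sum((sim_ccl2 - ccl2_series$ccl2_pg)^2) / w_ccl2
  }
  grid <- 0:100
  g <- vapply(grid, objective, numeric(1))
  i <- which.min(g)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(objective, c(lo, hi), tol = 1e-6)
  idx <- opt$minimum
  obj <- opt$objective
  if (g[i] < obj) { idx <- grid[i]; obj <- g[i] }
  fit_result(c(tolerance_index = idx), obj,
             nrow(tnf_series) + nrow(ccl2_series), TRUE,
             details = list(weights = c(tnf = w_tnf, ccl2 = w_ccl2)))
}
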