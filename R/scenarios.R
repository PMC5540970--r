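#' Tolerance-index scenario
#'
#' Describes a culture by its total monocyte count and a tolerance index:
#' the percentage of the initial population in the endotoxin-tolerant state.
#'
#' @param total_monocytes Total initial monocyte count (> 0).
#' @param tolerance_index Percentage in the ET state, between 0 and 100.
#' @param initial_lps Challenge dose, ng/ml.
#' @param horizon,output_step Simulation horizon and sampling, hours.
#' @return An object of class `tolerance_scenario`.
#' @export
tolerance_scenario <- function(total_monocytes = 1e6, tolerance_index = 0,
                               initial_lps = 0, horizon = 24,
                               output_step = 0.1) {
  if (!is.numeric(total_monocytes) || total_monocytes <= 0)
    stop("total_monocytes must be > 0", call. = FALSE)
  if (!is.numeric(tolerance_index) || tolerance_index < 0 ||
      tolerance_index > 100)
    stop("tolerance_index must lie in [0, 100]", call. = FALSE)
  structure(list(total_monocytes = total_monocytes,
                 tolerance_index = tolerance_index,
                 initial_lps = initial_lps, horizon = horizon,
                 output_step = output_step),
            class = "tolerance_scenario")
}

#' Expand a tolerance index into initial subset counts
#'
#' Initial resting monocytes are `total * (100 - index) / 100` and initial
#' ET monocytes `total * index / 100`; the proinflammatory pool starts at
#' zero because transit through the proinflammatory state is fast relative
#' to the sampling. Cytokines start at zero.
#'
#' @param ts A [tolerance_scenario()].
#' @return A [scenario()].
#' @examples
#' tolerance_index_to_initial_states(tolerance_scenario(1e6, 68, 5))
#' @export
tolerance_index_to_initial_states <- function(ts) {
  stopifnot(inherits(ts, "tolerance_scenario"))
  scenario(initial_resting = ts$total_monocytes *
             (100 - ts$tolerance_index) / 100,
           initial_proinflammatory = 0,
           initial_et = ts$total_monocytes * ts$tolerance_index / 100,
           initial_lps = ts$initial_lps, horizon = ts$horizon,
           output_step = ts$output_step)
}

PRESET_NAMES <- c("fig4_dose_response", "fig5_control", "fig5_et",
                  "fig6_tolerance", "sepsis")

#' Published experiment presets
#'
#' Returns the exact initial conditions of the named published scenario:
#' \describe{
#'   \item{fig4_dose_response}{five all-resting cultures of 1e6 monocytes
#'     challenged with 5, 0.25, 0.1, 0.05 or 0 ng/ml LPS (a named list of
#'     scenarios, unchallenged last).}
#'   \item{fig5_control}{1e6 resting monocytes, 5 ng/ml LPS.}
#'   \item{fig5_et}{the endotoxin-tolerance split 0 / 75,000 / 925,000
#'     (resting / proinflammatory / ET), 5 ng/ml LPS.}
#'   \item{fig6_tolerance}{1e6 monocytes at tolerance index 68, 5 ng/ml
#'     LPS (a [tolerance_scenario()]).}
#'   \item{sepsis}{as `fig6_tolerance` with a 16 h horizon, the sepsis
#'     readout time.}
#' }
#'
#' @param name One of the preset names above.
#' @return A [scenario()], [tolerance_scenario()], or named list of
#'   scenarios for `fig4_dose_response`.
#' @export
preset <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% PRESET_NAMES))
    stop("unknown preset; valid names: ",
         paste(PRESET_NAMES, collapse = ", "), call. = FALSE)
  switch(name,
    fig4_dose_response = {
      doses <- c(5, 0.25, 0.1, 0.05, 0)
      out <- lapply(doses, function(d)
        scenario(initial_resting = 1e6, initial_lps = d))
      names(out) <- paste0("lps_", doses)
      out
    },
    fig5_control = scenario(initial_resting = 1e6, initial_lps = 5),
    fig5_et = scenario(initial_resting = 0, initial_proinflammatory = 75000,
                       initial_et = 925000, initial_lps = 5),
    fig6_tolerance = tolerance_scenario(1e6, 68, 5),
    sepsis = tolerance_scenario(1e6, 68, 5, horizon = 16))
}

#' Measurement-noise specification for the synthetic generator
#'
#' @param additive_sd Additive Gaussian noise SD, in the units of the
#'   perturbed readout (pg for cytokines, percentage points for decay
#'   series).
#' @param multiplicative_cv Multiplicative Gaussian coefficient of
#'   variation (fraction).
#' @param replicates Number of replicate series (>= 1).
#' @param seed RNG seed; the generator is bit-reproducible given the seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(additive_sd = 0, multiplicative_cv = 0,
                       replicates = 1, seed = 1) {
  if (additive_sd < 0 || multiplicative_cv < 0)
    stop("noise magnitudes must be non-negative", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(list(additive_sd = additive_sd,
                 multiplicative_cv = multiplicative_cv,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

noisy <- function(y, noise) {
  z <- y * (1 + stats::rnorm(length(y), 0, noise$multiplicative_cv)) +
    stats::rnorm(length(y), 0, noise$additive_sd)
  pmax(z, 0)  # measured masses cannot be negative
}

#' Generate replicated synthetic cytokine time courses
#'
#' Simulates a scenario, samples TNF and CCL2 on an experimental time grid
#' and perturbs each replicate with `y * (1 + eps_mult) + eps_add`
#' (Gaussian, truncated at zero), emulating replicated supernatant
#' measurements. The default grid matches 24 h culture sampling.
#'
#' @param scn A [scenario()] or [tolerance_scenario()].
#' @param p A [model_parameters()] object.
#' @param noise A [noise_spec()].
#' @param times Sampling times, hours.
#' @param step Integration step, hours.
#' @return A list with `replicates` (long data frame: `time_h`, `replicate`,
#'   `tnf_pg`, `ccl2_pg`) and `summary` (per-time mean and SEM of both
#'   cytokines).
#' @export
generate_timecourse <- function(scn, p = model_parameters(),
                                noise = noise_spec(),
                                times = c(1, 2, 4, 8, 16, 24),
                                step = 0.005) {
  if (inherits(scn, "tolerance_scenario"))
    scn <- tolerance_index_to_initial_states(scn)
  stopifnot(inherits(scn, "scenario"), inherits(noise, "noise_spec"))
  if (max(times) > scn$horizon)
    scn$horizon <- max(times)
  tr <- simulate_scenario(scn, p, step = step, times = times)
  reps <- with_seed(noise$seed, {
    do.call(rbind, lapply(seq_len(noise$replicates), function(r)
      data.frame(time_h = tr$time_h, replicate = r,
                 tnf_pg = noisy(tr$tnf_pg, noise),
                 ccl2_pg = noisy(tr$ccl2_pg, noise))))
  })
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  agg <- function(col, f) tapply(reps[[col]], reps$time_h, f)
  summary <- data.frame(time_h = sort(unique(reps$time_h)),
                        tnf_mean = as.numeric(agg("tnf_pg", mean)),
                        tnf_sem = as.numeric(agg("tnf_pg", sem)),
                        ccl2_mean = as.numeric(agg("ccl2_pg", mean)),
                        ccl2_sem = as.numeric(agg("ccl2_pg", sem)))
  list(replicates = reps, summary = summary)
}

#' In-silico two-stimulus tolerization protocol
#'
#' Emulates the wet-lab protocol behind activation-rate estimation: cells
#' are stimulated with `lps_first` for `t_s` hours, washed (LPS set to zero
#' and accumulated cytokines discarded with the supernatant), rested 16 h in
#' medium, then re-challenged with 5 ng/ml LPS for 3 h; the TNF produced in
#' that window is expressed as a percentage of the unprimed (`t_s = 0`)
#' control. Segments are chained simulations; each segment's delay
#' pre-history is its own initial composition.
#'
#' @param lps_first First-stimulus dose, ng/ml.
#' @param t_s_grid First-stimulus durations, hours (0 is added if absent).
#' @param p A [model_parameters()] object.
#' @param noise A [noise_spec()]; noise acts on the percentage readout
#'   (`additive_sd` in percentage points).
#' @param second_dose,rest_h,challenge_h Protocol constants: re-challenge
#'   dose (ng/ml), rest duration and readout window (hours).
#' @param initial_resting Starting resting-monocyte count.
#' @param step Integration step, hours.
#' @return A decay-series data frame (`t_s_h`, `replicate`, `relative_pct`)
#'   consumable by [fit_decay()].
#' @export
generate_decay_protocol <- function(lps_first,
                                    t_s_grid = c(0, 0.25, 0.5, 1, 2, 4, 8, 16),
                                    p = model_parameters(),
                                    noise = noise_spec(), second_dose = 5,
                                    rest_h = 16, challenge_h = 3,
                                    initial_resting = 1e6, step = 0.005) {
  stopifnot(inherits(p, "model_parameters"), inherits(noise, "noise_spec"))
  if (lps_first < 0) stop("lps_first must be >= 0", call. = FALSE)
  t_s_grid <- sort(unique(c(0, t_s_grid)))

  end_state <- function(tr) {
    n <- nrow(tr)
    c(resting = tr$resting[n], proinflammatory = tr$proinflammatory[n],
      et = tr$et[n], lps = tr$lps_ng_ml[n], tnf = tr$tnf_pg[n],
      ccl2 = tr$ccl2_pg[n])
  }
  run <- function(state, lps, hours) {
    scn <- scenario(initial_resting = state[["resting"]],
                    initial_proinflammatory = state[["proinflammatory"]],
                    initial_et = state[["et"]], initial_lps = lps,
                    initial_tnf = state[["tnf"]],
                    initial_ccl2 = state[["ccl2"]],
                    horizon = hours, output_step = hours)
    end_state(simulate_scenario(scn, p, step = step, times = c(0, hours)))
  }
  tnf_readout <- function(t_s) {
    s <- c(resting = initial_resting, proinflammatory = 0, et = 0,
           lps = 0, tnf = 0, ccl2 = 0)
    if (t_s > 0) s <- run(s, lps_first, t_s)
    s[["lps"]] <- 0                       # wash: LPS carried over is nil
    s[["tnf"]] <- 0; s[["ccl2"]] <- 0     # supernatant replaced
    s <- run(s, 0, rest_h)
    s[["tnf"]] <- 0; s[["ccl2"]] <- 0     # fresh medium before re-challenge
    s <- run(s, second_dose, challenge_h)
    s[["tnf"]]
  }
  raw <- vapply(t_s_grid, tnf_readout, numeric(1))
  control <- raw[t_s_grid == 0]
  rel <- 100 * raw / control
  with_seed(noise$seed, {
    do.call(rbind, lapply(seq_len(noise$replicates), function(r)
      data.frame(t_s_h = t_s_grid, replicate = r,
                 relative_pct = noisy(rel, noise))))
  })
}
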