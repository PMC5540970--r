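fmt_num <- function(x) trimws(formatC(x, digits = 10, format = "g"))

#' Load model parameters from a JSON or YAML file
#'
#' The document may hold any subset of the 14 snake_case parameter names;
#' missing parameters are filled from the packaged defaults (with a notice),
#' unknown keys are rejected. The packaged file
#' `system.file("extdata", "default_parameters.json", package = "monotol")`
#' reproduces the reference values exactly.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [model_parameters()] object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("parameter file must hold a mapping", call. = FALSE)
  unknown <- setdiff(names(doc), PARAM_NAMES)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(PARAM_NAMES, names(doc))
  if (length(missing))
    message("filling ", length(missing),
            " missing parameter(s) from defaults: ",
            paste(missing, collapse = ", "))
  doc <- lapply(doc, as.numeric)
  do.call(model_parameters, doc)
}

#' Write model parameters to JSON
#' @param p A [model_parameters()] object.
#' @param path Output path.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "model_parameters"))
  jsonlite::write_json(p[PARAM_NAMES], path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

param_header <- function(p, seed = NULL) {
  h <- c("# monotol trajectory",
         paste0("# ", names(param_vector(p)), " = ",
                fmt_num(param_vector(p))))
  if (!is.null(seed)) h <- c(h, paste0("# seed = ", seed))
  h
}

#' Write a trajectory to CSV
#'
#' Comma-separated with a `#`-prefixed header block embedding the parameter
#' set (and optionally the seed) so the file is self-describing; numbers are
#' serialized with 10 significant digits.
#'
#' @param traj A trajectory from [simulate_scenario()].
#' @param path Output path.
#' @param flows Include the seven flow columns?
#' @param seed Optional seed to record in the header.
#' @export
write_trajectory_csv <- function(traj, path, flows = TRUE, seed = NULL) {
  stopifnot(inherits(traj, "monotol_trajectory"))
  p <- attr(traj, "parameters")
  cols <- c("time_h", "resting", "proinflammatory", "et", "lps_ng_ml",
            "tnf_pg", "ccl2_pg")
  if (flows) cols <- c(cols, grep("^flow_", names(traj), value = TRUE))
  df <- as.data.frame(traj)[, cols]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(param_header(p, seed), con)
  writeLines(paste(cols, collapse = ","), con)
  body <- apply(df, 1, function(r) paste(fmt_num(r), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#' @param path Input path.
#' @return A data frame (comment headers are skipped).
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Read a two-column dose-rate CSV (`lps_ng_ml,rate`)
#' @param path Input path.
#' @return A [dose_rate_table()].
#' @export
read_dose_rate_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  as_dose_rate_table(df)
}

#' Read a decay-series CSV (`t_s_h,relative_pct`)
#' @param path Input path.
#' @return A data frame consumable by [fit_decay()].
#' @export
read_decay_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("t_s_h", "relative_pct") %in% names(df)))
    stop("decay CSV needs columns t_s_h and relative_pct", call. = FALSE)
  df
}

#' Write a fit report to JSON
#'
#' Serializes estimates, SSE, point count, convergence flag and the fit
#' configuration held in `details`.
#'
#' @param fit A `monotol_fit`.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "monotol_fit"))
  rep <- list(estimates = as.list(fit$estimates), sse = fit$sse,
              n_points = fit$n_points, converged = fit$converged,
              details = fit$details)
  if (!is.null(seed)) rep$seed <- seed
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Packaged calibration fixtures
#'
#' Paths to the packaged reference tables: the empirical activation rates
#' per LPS dose (`"activation"`) and the estimated TNF synthesis rates per
#' dose (`"tnf"`), both as `lps_ng_ml,rate` CSV.
#'
#' @param which `"activation"` or `"tnf"`.
#' @return File path.
#' @export
fixture_path <- function(which = c("activation", "tnf")) {
  which <- match.arg(which)
  fn <- switch(which, activation = "activation_rates.csv",
               tnf = "tnf_synthesis_rates.csv")
  system.file("extdata", fn, package = "monotol", mustWork = TRUE)
}
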