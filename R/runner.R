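# File-based orchestration used by the command-line front end
# (inst/cli/epiquake): pool effects, run scenarios, compare reports.

#' Run manifest
#'
#' Provenance record attached to every report: the configuration echo,
#' seed, input files and package version, so any output can be regenerated
#' bit-identically.
#'
#' @param config A [scenario_config()] (or `NULL` for pooling runs).
#' @param inputs Named character vector of input file paths.
#' @return A named list.
#' @export
run_manifest <- function(config = NULL, inputs = character()) {
  list(
    package = "epiquake",
    version = as.character(packageVersion("epiquake")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    inputs = as.list(inputs),
    seed = if (!is.null(config)) config$seed,
    ses_mode = if (!is.null(config)) config$ses_mode,
    population = if (!is.null(config)) config$population,
    coefficient_source = if (!is.null(config)) config$death_coeffs$source[[1]],
    damage_state = if (!is.null(config)) as.list(config$damage_state)
  )
}

#' Pool a study-effects CSV to a pooled-effects CSV
#'
#' Reads a study table (see [read_study_effects()]), pools each
#' (factor, outcome) group with [pool_effects()] and writes the result.
#'
#' @param studies_csv Input CSV of study effects.
#' @param out_csv Output path for the pooled effects.
#' @param method tau^2 estimator, see [pool_effects()].
#' @return The pooled-effects tibble, invisibly.
#' @export
cmd_pool <- function(studies_csv, out_csv, method = "DL") {
  pooled <- pool_effects(read_study_effects(studies_csv), method = method)
  readr::write_csv(tidy(pooled), out_csv)
  invisible(pooled)
}

#' Run a casualty-estimation scenario from files
#'
#' Reads tract profiles, runs [estimate_casualties()] and writes a tally
#' CSV (one row per tract and severity, with counts and percentages) plus
#' a JSON report holding the city summary, the HAZUS comparison and the
#' run manifest.
#'
#' @param profiles_csv Input CSV of tract profiles.
#' @param out_csv Output tally CSV path.
#' @param out_json Optional output JSON report path.
#' @param config A [scenario_config()].
#' @return The `casualty_estimate`, invisibly.
#' @export
cmd_estimate <- function(profiles_csv, out_csv, out_json = NULL,
                         config = scenario_config()) {
  profiles <- read_tract_profiles(profiles_csv)
  est <- estimate_casualties(profiles, config)
  tally_out <- est$tally |>
    dplyr::mutate(pct = round(100 * .data$fraction, 2))
  readr::write_csv(tally_out, out_csv)
  if (!is.null(out_json)) {
    report <- list(
      city = est$city,
      comparison = compare_to_hazus(est),
      manifest = run_manifest(config, c(profiles = profiles_csv))
    )
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(est)
}

#' Compare a JSON report against the HAZUS reference rates
#'
#' Reads a report written by [cmd_estimate()] and returns the
#' percentage-point delta per severity between the integrated model and
#' the unadjusted HAZUS rates.
#'
#' @param report_json Path to a JSON report.
#' @return A tibble, as from [compare_to_hazus()].
#' @export
cmd_compare <- function(report_json) {
  report <- jsonlite::read_json(report_json, simplifyVector = TRUE)
  if (is.null(report$city)) abort("Report has no `city` summary.")
  compare_to_hazus(tibble::as_tibble(report$city))
}
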