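# End-to-end scenario estimation and result methods.

#' Estimate earthquake casualties for a set of census tracts
#'
#' The full pipeline: realise each tract's population (exact enumeration
#' cells or a seeded synthetic sample, per `config$population`), run the
#' fatal-severe-moderate-light cascade tract by tract, and aggregate a
#' resident-weighted city summary.
#'
#' @param profiles A tract-profile tibble (see [tiberias_tracts()]).
#' @param config A [scenario_config()].
#' @return A `casualty_estimate` object: a list with `tally` (per-tract
#'   counts and fractions per severity), `city` (resident-weighted summary
#'   with the HAZUS reference distribution) and `config`. Use [tidy()] for
#'   the tally, [glance()] for the city row, [autoplot()] for a figure and
#'   [compare_to_hazus()] for percentage-point deltas.
#' @examples
#' est <- estimate_casualties(tiberias_tracts(), scenario_config())
#' glance(est)
#' @export
estimate_casualties <- function(profiles, config = scenario_config()) {
  profiles <- validate_tract_profiles(profiles)
  pop <- switch(config$population,
    cells = enumerate_cells(profiles, ses_mode = config$ses_mode,
                            ses_rate = config$ses_rate),
    sampled = generate_individuals(profiles, ses_mode = config$ses_mode,
                                   seed = config$seed, ses_rate = config$ses_rate)
  )
  tally <- pop |>
    dplyr::group_split(.data$tract_id) |>
    purrr::map_dfr(run_cascade, config = config) |>
    dplyr::arrange(match(.data$tract_id, profiles$tract_id))
  structure(
    list(tally = tally, city = aggregate_city(tally), config = config),
    class = "casualty_estimate"
  )
}

#' @method tidy casualty_estimate
#' @export
tidy.casualty_estimate <- function(x, ...) {
  x$tally
}

#' @method glance casualty_estimate
#' @export
glance.casualty_estimate <- function(x, ...) {
  wide <- x$city |>
    dplyr::select("severity", "pct") |>
    tidyr::pivot_wider(names_from = "severity", values_from = "pct",
                       names_glue = "pct_{severity}")
  dplyr::bind_cols(
    tibble::tibble(
      n_tracts = length(unique(x$tally$tract_id)),
      n_residents = sum(x$tally$count)
    ),
    wide
  )
}

#' @export
print.casualty_estimate <- function(x, ...) {
  cat("Integrated earthquake casualty estimate\n")
  cat(sprintf("  %d tract(s), %d residents; population = %s, ses_mode = %s, seed = %d\n",
              length(unique(x$tally$tract_id)), sum(x$tally$count),
              x$config$population, x$config$ses_mode, x$config$seed))
  cat("City summary (resident-weighted):\n")
  print(dplyr::mutate(x$city, pct = round(.data$pct, 1)), n = Inf)
  invisible(x)
}

#' Compare an estimate with the unadjusted HAZUS rates
#'
#' Percentage-point difference per severity between the integrated model's
#' resident-weighted city distribution and the HAZUS collapse-scenario
#' reference rates.
#'
#' @param x A `casualty_estimate`, or a city summary tibble with columns
#'   `severity`, `pct` and `hazus_pct`.
#' @return A tibble with `severity`, `model_pct`, `hazus_pct`,
#'   `delta_pct_points`.
#' @export
compare_to_hazus <- function(x) {
  city <- if (inherits(x, "casualty_estimate")) x$city else x
  needed <- c("severity", "pct", "hazus_pct")
  missing <- setdiff(needed, names(city))
  if (length(missing) > 0) {
    abort(paste0("City summary is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  city |>
    dplyr::transmute(
      severity = .data$severity,
      model_pct = .data$pct,
      hazus_pct = .data$hazus_pct,
      delta_pct_points = .data$pct - .data$hazus_pct
    )
}

#' Plot a casualty estimate
#'
#' Per-tract stacked composition of casualty severities, with the
#' resident-weighted city distribution and the unadjusted HAZUS reference
#' as additional bars.
#'
#' @param object A `casualty_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot casualty_estimate
#' @export
autoplot.casualty_estimate <- function(object, ...) {
  lev <- c("uninjured", severity_levels())
  per_tract <- object$tally |>
    dplyr::transmute(unit = .data$tract_id, severity = .data$severity,
                     pct = 100 * .data$fraction)
  city <- object$city |>
    dplyr::transmute(unit = "city (model)", severity = .data$severity,
                     pct = .data$pct)
  hazus <- hazus_reference() |>
    dplyr::transmute(unit = "HAZUS rates", severity = .data$severity,
                     pct = .data$hazus_pct)
  df <- dplyr::bind_rows(per_tract, city, hazus) |>
    dplyr::mutate(
      severity = factor(.data$severity, levels = lev),
      unit = factor(.data$unit, levels = c(unique(per_tract$unit),
                                           "city (model)", "HAZUS rates"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$unit, y = .data$pct,
                                   fill = .data$severity)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = NULL, y = "% of residents", fill = "severity",
                  title = "Casualty composition by census tract") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot pooled effects
#'
#' Pooled odds ratios with 95% confidence intervals per risk factor and
#' outcome, on a log scale.
#'
#' @param object A `pooled_effects` table from [pool_effects()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pooled_effects
#' @export
autoplot.pooled_effects <- function(object, ...) {
  df <- dplyr::mutate(tidy(object),
                      label = paste(.data$factor, .data$outcome, sep = " / "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pooled_or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "pooled odds ratio (95% CI)", y = NULL,
                  title = "Pooled risk-factor effects") +
    ggplot2::theme_minimal()
}
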