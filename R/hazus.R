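# HAZUS casualty-rate table and conversion of rates to logistic intercepts.

#' HAZUS casualty rates by damage state and injury severity
#'
#' Fraction of building occupants expected to sustain an injury of each
#' severity (light, moderate, severe, fatal) for each structural damage
#' state. The packaged table is for reinforced-concrete structures, the
#' common residential type in Israel; `read_casualty_rates()` loads an
#' alternative table in the same dialect (CSV with a `damage_state` column
#' and one percent-valued column per severity).
#'
#' @param path Path to a CSV rate table in percent.
#' @return A tibble with columns `damage_state`, `severity`, `rate`
#'   (fraction in \[0, 1\]).
#' @examples
#' casualty_rates()
#' @export
casualty_rates <- function() {
  read_casualty_rates(system.file("extdata", "hazus_casualty_rates.csv",
                                  package = "epiquake", mustWork = TRUE))
}

#' @rdname casualty_rates
#' @export
read_casualty_rates <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("damage_state", severity_levels()), names(wide))
  if (length(missing) > 0) {
    abort(paste0("Rate table is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  tbl <- wide |>
    tidyr::pivot_longer(dplyr::all_of(severity_levels()),
                        names_to = "severity", values_to = "rate") |>
    dplyr::mutate(rate = .data$rate / 100)  # table dialect is percent
  bad_state <- !tbl$damage_state %in% damage_states()
  if (any(bad_state)) {
    abort(sprintf("Unknown damage state '%s' in rate table.",
                  tbl$damage_state[bad_state][1]))
  }
  check_fraction(tbl$rate, "rate")
  tbl
}

#' Look up a casualty rate
#'
#' @param table A rate table from [casualty_rates()].
#' @param state A damage state (see [damage_states()]).
#' @param severity An injury severity (see [severity_levels()]).
#' @return The rate as a fraction in \[0, 1\].
#' @examples
#' casualty_rate(casualty_rates(), "complete_collapse", "fatal")  # 0.10
#' @export
casualty_rate <- function(table, state, severity) {
  match_enum(state, damage_states(), "state")
  match_enum(severity, severity_levels(), "severity")
  row <- table[table$damage_state == state & table$severity == severity, ]
  if (nrow(row) != 1) {
    abort(sprintf("Rate table has no entry for (%s, %s).", state, severity))
  }
  row$rate[[1]]
}

#' Convert a casualty rate to a logistic intercept
#'
#' The baseline intercept is the logit of the damage-state casualty rate,
#' `beta0 = ln(rate / (1 - rate))`: with all risk-factor indicators at
#' zero the model then reproduces the HAZUS rate exactly (e.g. a 10%
#' fatality rate under collapse gives `beta0 = ln(1/9) = -2.197`). A rate
#' of exactly zero is a structural zero -- no casualty of that severity can
#' occur in that damage state regardless of risk factors -- and is encoded
#' as `-Inf`, which forces probability 0 through the inverse logit.
#' Vectorised.
#'
#' @param rate Casualty rate(s), fractions with `0 <= rate < 1`.
#' @return The intercept(s) on the logit scale; `-Inf` marks a structural
#'   zero.
#' @examples
#' baseline_intercept(0.10)  # -2.197
#' baseline_intercept(0)     # -Inf (structural zero)
#' @export
baseline_intercept <- function(rate) {
  if (any(is.na(rate) | rate < 0 | rate >= 1)) {
    abort("`rate` must satisfy 0 <= rate < 1.")
  }
  ifelse(rate == 0, -Inf, qlogis(rate))
}

#' Unadjusted HAZUS collapse-scenario severity percentages
#'
#' The reference casualty distribution when every structure collapses and
#' no human-related factors are modelled: the collapse-state rates applied
#' marginally (40% light, 20% moderate, 5% severe, 10% fatal) with the
#' remaining 25% uninjured.
#'
#' @return A tibble with columns `severity` and `hazus_pct`.
#' @export
hazus_reference <- function() {
  tibble::tibble(
    severity = c("fatal", "severe", "moderate", "light", "uninjured"),
    hazus_pct = c(10, 5, 20, 40, 25)
  )
}
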