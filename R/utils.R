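# Shared enumerations and small helpers.

#' Risk factors, damage states and injury severities
#'
#' Canonical level sets used throughout the package. `severity_levels()`
#' is ordered from least to most severe (light < moderate < severe <
#' fatal); the cascade visits them in the reverse order.
#'
#' @return A character vector of levels.
#' @export
risk_factors <- function() {
  c("age_over_65", "female", "disability", "low_ses")
}

#' @rdname risk_factors
#' @export
damage_states <- function() {
  c("slight", "moderate", "severe", "complete_no_collapse", "complete_collapse")
}

#' @rdname risk_factors
#' @export
severity_levels <- function() {
  c("light", "moderate", "severe", "fatal")
}

#' @rdname risk_factors
#' @export
outcome_classes <- function() {
  c("death", "injury")
}

# Columns carrying the dichotomous risk-factor indicators, in the order
# matching coefficient sets (beta_age, beta_female, beta_disability, beta_ses).
indicator_cols <- function() {
  c("x_age", "x_female", "x_disabled", "x_low_ses")
}

# round half away from zero (arguments here are always >= 0)
round_half_away <- function(x) {
  floor(x + 0.5)
}

# validate that `x` is a single value from `choices`
match_enum <- function(x, choices, what) {
  if (length(x) != 1 || !x %in% choices) {
    abort(sprintf(
      "`%s` must be one of %s, not %s.",
      what, paste0("'", choices, "'", collapse = ", "),
      paste0("'", as.character(x), "'", collapse = ", ")
    ))
  }
  x
}

check_fraction <- function(x, what, allow_na = FALSE) {
  bad <- if (allow_na) !is.na(x) & (x < 0 | x > 1) else is.na(x) | x < 0 | x > 1
  if (any(bad)) {
    abort(sprintf("`%s` must lie in [0, 1]; offending value(s): %s.",
                  what, paste(x[bad], collapse = ", ")))
  }
  invisible(x)
}
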