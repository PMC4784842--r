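# Per-individual casualty probabilities and the hierarchical severity cascade.

#' Probability of a casualty outcome for each individual
#'
#' Evaluates the logistic model
#' `p = 1 / (1 + exp(-(beta0 + beta1*X1 + beta2*X2 + beta3*X3 + beta4*X4)))`
#' where `beta0` is the logit of the damage-state casualty rate (see
#' [baseline_intercept()]) and the remaining coefficients are pooled log
#' odds ratios for age over 65, female gender, physical disability and low
#' socioeconomic status. A structural-zero intercept (`-Inf`) gives
#' probability 0 for every individual.
#'
#' @param individuals A tibble with 0/1 columns `x_age`, `x_female`,
#'   `x_disabled`, `x_low_ses` (individuals or enumeration cells).
#' @param beta0 Baseline intercept on the logit scale (may be `-Inf`).
#' @param coeffs A [coefficient_set()].
#' @return Numeric vector of probabilities, one per row.
#' @examples
#' x <- tibble::tibble(x_age = 0, x_female = 0, x_disabled = 0, x_low_ses = 0)
#' injury_probability(x, baseline_intercept(0.10), coefficient_set("death"))
#' @export
injury_probability <- function(individuals, beta0, coeffs) {
  cols <- indicator_cols()
  missing <- setdiff(cols, names(individuals))
  if (length(missing) > 0) {
    abort(paste0("Missing indicator column(s): ", paste(missing, collapse = ", "), "."))
  }
  X <- as.matrix(individuals[cols])
  if (length(X) > 0 && !all(X %in% c(0, 1))) {
    abort("Risk-factor indicators must be strictly 0 or 1.")
  }
  lp <- beta0 + as.vector(X %*% coef_vector(coeffs))
  plogis(lp)
}

#' Integer casualty count from individual probabilities
#'
#' The expected number of casualties at a cascade step is the sum of the
#' individual probabilities, `E = sum(p)`; the reported count is that
#' expectation rounded to an integer (half away from zero by default, or
#' truncated with `rounding = "floor"`), never exceeding the pool size.
#'
#' @param probabilities Probabilities in \[0, 1\].
#' @param rounding `"nearest"` (default) or `"floor"`.
#' @return A non-negative integer count.
#' @examples
#' expected_count(rep(0.1, 100))  # 10
#' @export
expected_count <- function(probabilities, rounding = c("nearest", "floor")) {
  rounding <- match.arg(rounding)
  if (length(probabilities) == 0) return(0L)
  check_fraction(probabilities, "probabilities")
  e <- sum(probabilities)
  n <- switch(rounding, nearest = round_half_away(e), floor = floor(e))
  as.integer(min(n, length(probabilities)))
}

#' Scenario configuration for the casualty cascade
#'
#' Bundles everything a cascade run needs: the damage state (a single
#' state applied everywhere, or a named vector `tract_id -> state`), the
#' death and injury coefficient sets, the casualty-rate table, the
#' population realisation (`"cells"` for exact expected counts under
#' independence, `"sampled"` for a seeded synthetic population), the
#' socioeconomic coding policy and the count rounding rule.
#'
#' @param damage_state A damage state, or a named character vector mapping
#'   tract ids to damage states.
#' @param death_coeffs,injury_coeffs [coefficient_set()] rows for the fatal
#'   step and the three injury steps.
#' @param rate_table A rate table from [casualty_rates()].
#' @param population `"cells"` or `"sampled"`.
#' @param ses_mode,ses_rate Socioeconomic policy, see
#'   [generate_individuals()].
#' @param rounding Count rounding rule, see [expected_count()].
#' @param seed Integer seed (used when `population = "sampled"`).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(damage_state = "complete_collapse",
                            death_coeffs = coefficient_set("death"),
                            injury_coeffs = coefficient_set("injury"),
                            rate_table = casualty_rates(),
                            population = c("cells", "sampled"),
                            ses_mode = "all_one",
                            ses_rate = NULL,
                            rounding = c("nearest", "floor"),
                            seed = 1L) {
  if (is.null(names(damage_state))) {
    vapply(damage_state, match_enum, character(1),
           choices = damage_states(), what = "damage_state")
  } else {
    vapply(unname(damage_state), match_enum, character(1),
           choices = damage_states(), what = "damage_state")
  }
  structure(
    list(
      damage_state = damage_state,
      death_coeffs = death_coeffs,
      injury_coeffs = injury_coeffs,
      rate_table = rate_table,
      population = match.arg(population),
      ses_mode = ses_mode,
      ses_rate = ses_rate,
      rounding = match.arg(rounding),
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

# damage state for one tract (global state or per-tract map)
resolve_damage_state <- function(config, tract_id) {
  ds <- config$damage_state
  if (is.null(names(ds))) {
    if (length(ds) != 1) abort("Unnamed `damage_state` must be a single state.")
    return(ds)
  }
  if (!tract_id %in% names(ds)) {
    abort(sprintf("No damage state configured for tract '%s'.", tract_id))
  }
  ds[[tract_id]]
}

#' Run the hierarchical severity cascade on one tract's population
#'
#' Assigns residents to casualty severities in decreasing order of
#' severity: fatal, then severe, moderate and light. At each step the
#' casualty probability of every remaining resident is computed with the
#' intercept for the (damage state, severity) casualty rate -- death
#' coefficients for the fatal step, injury coefficients otherwise -- the
#' expected count `E = sum(p)` determines the number assigned, and the
#' residents with the highest probabilities are removed first (the
#' concept: accumulating risk factors push an individual toward the more
#' severe outcome). Whoever remains after the light step is uninjured.
#'
#' With a sampled population (rows are individuals) whole residents are
#' removed; ties in probability are broken by the original row order, so a
#' run is deterministic. With enumeration cells (a `weight` column)
#' fractional weight is removed from the highest-probability cells and
#' only the reported counts are rounded; the uninjured count balances the
#' tract total so counts always sum to the population.
#'
#' @param population One tract's individuals or cells (single `tract_id`).
#' @param config A [scenario_config()].
#' @return A one-tract tally tibble: `tract_id`, `severity` (fatal, severe,
#'   moderate, light, uninjured), `count`, `fraction`.
#' @export
run_cascade <- function(population, config) {
  ids <- unique(population$tract_id)
  if (length(ids) != 1) {
    abort("`run_cascade()` expects a single tract; use `estimate_casualties()` for many.")
  }
  state <- resolve_damage_state(config, ids)
  cellwise <- "weight" %in% names(population)
  steps <- rev(severity_levels())  # fatal, severe, moderate, light

  if (cellwise) {
    w <- population$weight
    n_total <- sum(w)
    counts_exact <- setNames(numeric(4), steps)
    for (s in steps) {
      b0 <- baseline_intercept(casualty_rate(config$rate_table, state, s))
      cf <- if (s == "fatal") config$death_coeffs else config$injury_coeffs
      p <- injury_probability(population, b0, cf)
      e <- sum(w * p)
      w <- remove_weight(w, p, e)
      counts_exact[s] <- e
    }
    counts <- round_counts(counts_exact, config$rounding)
    uninjured <- round(n_total) - sum(counts)
    if (uninjured < 0) abort("Rounded severity counts exceed the tract population.")
  } else {
    pool <- population
    n_total <- nrow(pool)
    counts <- setNames(integer(4), steps)
    for (s in steps) {
      b0 <- baseline_intercept(casualty_rate(config$rate_table, state, s))
      cf <- if (s == "fatal") config$death_coeffs else config$injury_coeffs
      p <- injury_probability(pool, b0, cf)
      n_s <- expected_count(p, config$rounding)
      # ties in p are broken by insertion order, so runs are reproducible
      ord <- order(-p, seq_along(p))
      keep <- if (n_s > 0) ord[-seq_len(n_s)] else ord
      pool <- pool[sort(keep), , drop = FALSE]
      counts[s] <- n_s
    }
    uninjured <- nrow(pool)
  }

  sev <- c(steps, "uninjured")
  n_round <- round(n_total)
  tibble::tibble(
    tract_id = ids,
    severity = sev,
    count = as.integer(c(counts, uninjured)),
    fraction = unname(c(counts, uninjured)) / n_round
  )
}

# remove `amount` of weight from the highest-probability cells first
remove_weight <- function(w, p, amount) {
  for (i in order(-p, seq_along(p))) {
    if (amount <= 0) break
    take <- min(w[i], amount)
    w[i] <- w[i] - take
    amount <- amount - take
  }
  w
}

round_counts <- function(counts, rounding) {
  switch(rounding,
         nearest = round_half_away(counts),
         floor = floor(counts))
}

#' Aggregate tract tallies into a city summary
#'
#' Resident-weighted totals and percentages per severity across tracts,
#' joined with the unadjusted HAZUS collapse-scenario reference
#' distribution (see [hazus_reference()]).
#'
#' @param tallies A tally tibble from [run_cascade()] or
#'   [estimate_casualties()] (one or more tracts).
#' @return A tibble with `severity`, `count`, `pct` and `hazus_pct`.
#' @export
aggregate_city <- function(tallies) {
  if (nrow(tallies) == 0) abort("No tallies to aggregate.")
  total <- sum(tallies$count)
  tallies |>
    dplyr::group_by(.data$severity) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(pct = 100 * .data$count / total) |>
    dplyr::left_join(hazus_reference(), by = "severity") |>
    dplyr::arrange(match(.data$severity, c(rev(severity_levels()), "uninjured")))
}
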