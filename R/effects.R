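# Study effects: published odds ratios and their random-effects pooling.

#' Published study effects for the four human-related risk factors
#'
#' Odds ratios (with 95% confidence intervals) reported by epidemiological
#' studies of earthquake-induced death and injury, one row per study and
#' risk factor. Four dichotomous factors are covered: age over 65, female
#' gender, physical disability and low socioeconomic status. These are the
#' inputs to [pool_effects()].
#'
#' @param path Path to a CSV file with columns `study_label`, `event_label`,
#'   `factor`, `outcome`, `odds_ratio`, `ci_low`, `ci_high`. `study_effects()`
#'   reads the packaged table; `read_study_effects()` reads a user file in
#'   the same dialect.
#' @return A tibble with one validated row per study effect.
#' @examples
#' study_effects()
#' @export
study_effects <- function() {
  read_study_effects(system.file("extdata", "risk_factor_studies.csv",
                                 package = "epiquake", mustWork = TRUE))
}

#' @rdname study_effects
#' @export
read_study_effects <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_study_effects(df)
}

#' Validate a table of study effects
#'
#' Checks column presence, enumerations and confidence-interval geometry
#' (`0 < ci_low <= odds_ratio <= ci_high`, with `ci_low < ci_high`). Error
#' messages name the offending study.
#'
#' @param df A data frame of study effects.
#' @return The input as a tibble, invisibly validated.
#' @export
validate_study_effects <- function(df) {
  needed <- c("study_label", "factor", "outcome", "odds_ratio", "ci_low", "ci_high")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("Study table is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  if (nrow(df) == 0) {
    abort("Study table is empty: at least one study effect is required.")
  }
  bad_factor <- !df$factor %in% risk_factors()
  if (any(bad_factor)) {
    abort(sprintf("Unknown risk factor '%s' for study '%s'.",
                  df$factor[bad_factor][1], df$study_label[bad_factor][1]))
  }
  bad_outcome <- !df$outcome %in% outcome_classes()
  if (any(bad_outcome)) {
    abort(sprintf("Unknown outcome '%s' for study '%s'.",
                  df$outcome[bad_outcome][1], df$study_label[bad_outcome][1]))
  }
  bad_ci <- with(df, !(ci_low > 0 & ci_low <= odds_ratio &
                         odds_ratio <= ci_high & ci_low < ci_high))
  if (any(bad_ci)) {
    abort(sprintf(
      "Invalid odds ratio / CI for study '%s' (%s, %s): need 0 < ci_low <= OR <= ci_high with ci_low < ci_high.",
      df$study_label[bad_ci][1], df$factor[bad_ci][1], df$outcome[bad_ci][1]
    ))
  }
  tibble::as_tibble(df)
}

#' Log odds ratio and its standard error from a printed confidence interval
#'
#' Published effects usually report only the odds ratio and a 95% CI. On the
#' log scale the interval is treated as symmetric normal, so
#' `se = (ln(ci_high) - ln(ci_low)) / (2 * 1.96)`. Vectorised.
#'
#' @param or,ci_low,ci_high Positive odds ratio and its 95% CI bounds.
#' @return A tibble with columns `log_or` and `se_log_or`.
#' @examples
#' logor_from_ci(1.6, 1.0, 2.5)
#' @export
logor_from_ci <- function(or, ci_low, ci_high) {
  bad <- !(ci_low > 0 & ci_low <= or & or <= ci_high & ci_low < ci_high)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "Invalid OR/CI at position %d (or=%s, ci=[%s, %s]): need 0 < ci_low <= OR <= ci_high with ci_low < ci_high.",
      i, or[i], ci_low[i], ci_high[i]
    ))
  }
  tibble::tibble(
    log_or = log(or),
    se_log_or = (log(ci_high) - log(ci_low)) / (2 * z95())
  )
}

# Wald CI multiplier used throughout (95%, normal approximation); kept at
# the conventional 1.96 so se = (ln hi - ln lo)/3.92 exactly.
z95 <- function() 1.96

#' Pool study effects with a random-effects meta-analysis
#'
#' Pools the log odds ratios of each (risk factor, outcome) group with a
#' random-effects model; the between-study variance tau^2 is estimated by
#' the DerSimonian-Laird moment estimator (the default; fitting is
#' delegated to [metafor::rma()]). Standard errors come from the printed
#' confidence intervals via [logor_from_ci()]. A group with a single study
#' passes through its printed OR and CI unchanged, with `tau_sq = 0`.
#'
#' @param studies A data frame of study effects (see [study_effects()]).
#' @param method Estimator for tau^2, passed to [metafor::rma()]; `"DL"`
#'   (DerSimonian-Laird) by default.
#' @return A `pooled_effects` tibble with one row per (factor, outcome):
#'   `pooled_or`, `ci_low`, `ci_high`, `log_or`, `se_log_or`, `tau_sq`,
#'   `q_stat`, `n_studies`.
#' @examples
#' study_effects() |> pool_effects()
#' @export
pool_effects <- function(studies, method = "DL") {
  studies <- validate_study_effects(studies)
  out <- studies |>
    dplyr::group_by(.data$factor, .data$outcome) |>
    dplyr::group_modify(~ pool_one(.x, method = method)) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$factor, risk_factors()), .data$outcome)
  class(out) <- c("pooled_effects", class(out))
  attr(out, "method") <- method
  out
}

# Pool one homogeneous (factor, outcome) group.
pool_one <- function(df, method) {
  sc <- logor_from_ci(df$odds_ratio, df$ci_low, df$ci_high)
  k <- nrow(df)
  if (k == 1) {
    # single study: printed values pass through unchanged
    return(tibble::tibble(
      pooled_or = df$odds_ratio, ci_low = df$ci_low, ci_high = df$ci_high,
      log_or = sc$log_or, se_log_or = sc$se_log_or,
      tau_sq = 0, q_stat = 0, n_studies = 1L
    ))
  }
  fit <- metafor::rma(yi = sc$log_or, sei = sc$se_log_or, method = method)
  mu <- as.numeric(fit$beta)
  se <- fit$se
  tibble::tibble(
    pooled_or = exp(mu),
    ci_low = exp(mu - z95() * se),
    ci_high = exp(mu + z95() * se),
    log_or = mu, se_log_or = se,
    tau_sq = fit$tau2, q_stat = fit$QE, n_studies = k
  )
}

#' @method tidy pooled_effects
#' @export
tidy.pooled_effects <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pooled_effects")
  attr(out, "method") <- NULL
  tibble::as_tibble(out)
}

#' @method glance pooled_effects
#' @export
glance.pooled_effects <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x),
    n_studies = sum(x$n_studies),
    max_tau_sq = max(x$tau_sq),
    method = attr(x, "method") %||% "DL"
  )
}

#' Logistic coefficient sets for the casualty model
#'
#' Assembles the four log odds-ratio coefficients (beta_age, beta_female,
#' beta_disability, beta_ses) for one outcome class. With
#' `source = "canonical"` the published equation values are returned: for
#' death `(1.073, 0.182, 0.609, 0.788)` and for injury
#' `(ln 1.3, ln 1.7, 0.609, 0.788)` -- no injury-specific effects exist for
#' disability and socioeconomic status, so the death effects are reused.
#' With `source = "pooled"` the betas are `ln(pooled_or)` from a
#' [pool_effects()] table (injury again borrows the death effects for the
#' last two factors). `source = "custom"` takes `betas` verbatim.
#'
#' @param outcome `"death"` or `"injury"`.
#' @param source `"canonical"`, `"pooled"` or `"custom"`.
#' @param pooled A `pooled_effects` table (required for `source = "pooled"`).
#' @param betas Named or positional numeric vector of length 4 (for
#'   `source = "custom"`), in the order age, female, disability, ses.
#' @return A one-row `coefficient_set` tibble with columns `outcome`,
#'   `beta_age`, `beta_female`, `beta_disability`, `beta_ses`, `source`.
#' @examples
#' coefficient_set("death")
#' coefficient_set("injury", source = "pooled", pooled = pool_effects(study_effects()))
#' @export
coefficient_set <- function(outcome = c("death", "injury"),
                            source = c("canonical", "pooled", "custom"),
                            pooled = NULL, betas = NULL) {
  outcome <- match.arg(outcome)
  source <- match.arg(source)
  b <- switch(source,
    canonical = if (outcome == "death") {
      c(1.073, 0.182, 0.609, 0.788)
    } else {
      c(log(1.3), log(1.7), 0.609, 0.788)
    },
    pooled = betas_from_pooled(outcome, pooled),
    custom = {
      if (is.null(betas) || length(betas) != 4 || !all(is.finite(betas))) {
        abort("`betas` must be 4 finite values (age, female, disability, ses).")
      }
      as.numeric(betas)
    }
  )
  tibble::new_tibble(
    tibble::tibble(outcome = outcome, beta_age = b[1], beta_female = b[2],
                   beta_disability = b[3], beta_ses = b[4], source = source),
    class = "coefficient_set"
  )
}

betas_from_pooled <- function(outcome, pooled) {
  if (is.null(pooled)) abort("`pooled` is required when source = 'pooled'.")
  pick <- function(fct, oc) {
    row <- pooled[pooled$factor == fct & pooled$outcome == oc, ]
    if (nrow(row) == 0) NA_real_ else row$log_or[[1]]
  }
  death <- vapply(risk_factors(), pick, numeric(1), oc = "death")
  missing <- risk_factors()[is.na(death)]
  if (length(missing) > 0) {
    abort(paste0("Pooled death effect missing for factor(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  if (outcome == "death") return(unname(death))
  inj <- vapply(risk_factors(), pick, numeric(1), oc = "injury")
  # injury equations reuse the death effects for disability and SES; age and
  # female fall back to death only if no injury estimate exists
  c(
    if (is.na(inj[["age_over_65"]])) death[["age_over_65"]] else inj[["age_over_65"]],
    if (is.na(inj[["female"]])) death[["female"]] else inj[["female"]],
    death[["disability"]],
    death[["low_ses"]]
  )
}

# coefficient vector in indicator order, for the linear predictor
coef_vector <- function(coeffs) {
  stopifnot(inherits(coeffs, "coefficient_set") || all(
    c("beta_age", "beta_female", "beta_disability", "beta_ses") %in% names(coeffs)
  ))
  c(coeffs$beta_age[[1]], coeffs$beta_female[[1]],
    coeffs$beta_disability[[1]], coeffs$beta_ses[[1]])
}
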