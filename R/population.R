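# Tract profiles and synthetic populations carrying four binary risk factors.

#' Census-tract profiles for the city of Tiberias
#'
#' The twelve census tracts of Tiberias (some merged in pairs to match the
#' building-stock catalogue) with resident counts and the marginal rates of
#' the dichotomous risk factors: fraction over age 65, fraction female and
#' fraction physically disabled. `sei_rank` (socioeconomic index rank) and
#' `above_avg_salary` (whether the tract's average annual income exceeds
#' the national average) are descriptive metadata; individual-level
#' socioeconomic coding is chosen via `ses_mode` when a population is
#' realised.
#'
#' @param path Path to a CSV of tract profiles with columns `tract_id`,
#'   `n_residents`, `frac_over_65`, `frac_female`, `frac_disabled` and
#'   optionally `frac_low_ses`, `sei_rank`, `above_avg_salary`.
#' @return A tibble with one row per tract.
#' @examples
#' tiberias_tracts()
#' @export
tiberias_tracts <- function() {
  read_tract_profiles(system.file("extdata", "tiberias_tracts.csv",
                                  package = "epiquake", mustWork = TRUE))
}

#' @rdname tiberias_tracts
#' @export
read_tract_profiles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(tract_id = readr::col_character()))
  validate_tract_profiles(df)
}

# mean female fraction used when a tract's own value is missing
default_female_fraction <- function() 0.498

validate_tract_profiles <- function(df) {
  needed <- c("tract_id", "n_residents", "frac_over_65", "frac_female", "frac_disabled")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("Tract profile table is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  if (any(is.na(df$n_residents) | df$n_residents < 1)) {
    abort("`n_residents` must be a positive integer for every tract.")
  }
  check_fraction(df$frac_over_65, "frac_over_65")
  check_fraction(df$frac_female, "frac_female", allow_na = TRUE)
  check_fraction(df$frac_disabled, "frac_disabled")
  if ("frac_low_ses" %in% names(df)) check_fraction(df$frac_low_ses, "frac_low_ses")
  df <- dplyr::mutate(
    df,
    tract_id = as.character(.data$tract_id),
    frac_female = dplyr::coalesce(.data$frac_female, default_female_fraction())
  )
  tibble::as_tibble(df)
}

# per-tract probability that the low-SES indicator is 1
ses_probability <- function(profile, ses_mode, ses_rate = NULL) {
  switch(ses_mode,
    all_one = 1,
    all_zero = 0,
    per_tract_flag = {
      if (!"above_avg_salary" %in% names(profile)) {
        abort("ses_mode 'per_tract_flag' needs an `above_avg_salary` column.")
      }
      as.numeric(!profile$above_avg_salary)
    },
    bernoulli = {
      p <- ses_rate %||% profile[["frac_low_ses"]]
      if (is.null(p) || any(is.na(p))) {
        abort("ses_mode 'bernoulli' needs `ses_rate` or a `frac_low_ses` column.")
      }
      check_fraction(p, "ses rate")
      p
    },
    abort(sprintf("Unknown ses_mode '%s'.", ses_mode))
  )
}

#' Generate a synthetic population from tract marginals
#'
#' Realises `n_residents` individuals per tract, each carrying four binary
#' risk-factor indicators (`x_age`, `x_female`, `x_disabled`, `x_low_ses`)
#' drawn independently as Bernoulli variables matching the tract marginals.
#' The socioeconomic indicator is not published at tract level, so its
#' coding is a policy: `ses_mode = "all_one"` (default) marks every
#' resident as low-SES, consistent with the city's below-average
#' socioeconomic ranking; `"all_zero"` marks none; `"per_tract_flag"` uses
#' the tract's `above_avg_salary` flag; `"bernoulli"` draws from `ses_rate`
#' (or a `frac_low_ses` column).
#'
#' Identical `seed` and inputs give an identical population.
#'
#' @param profiles A tract-profile tibble (see [tiberias_tracts()]); one or
#'   more rows.
#' @param ses_mode Socioeconomic coding policy, see Details.
#' @param seed Integer seed controlling the draws.
#' @param ses_rate Optional Bernoulli rate for `ses_mode = "bernoulli"`.
#' @return A tibble of individuals: `tract_id` plus the four 0/1 indicator
#'   columns, `sum(n_residents)` rows.
#' @examples
#' tiberias_tracts() |> dplyr::slice(1) |> generate_individuals(seed = 1)
#' @export
generate_individuals <- function(profiles, ses_mode = "all_one", seed = 1L,
                                 ses_rate = NULL) {
  profiles <- validate_tract_profiles(profiles)
  set.seed(seed)
  purrr::map_dfr(
    seq_len(nrow(profiles)),
    function(i) {
      pr <- profiles[i, ]
      n <- pr$n_residents
      p_ses <- ses_probability(pr, ses_mode, ses_rate)
      tibble::tibble(
        tract_id = pr$tract_id,
        x_age = stats::rbinom(n, 1L, pr$frac_over_65),
        x_female = stats::rbinom(n, 1L, pr$frac_female),
        x_disabled = stats::rbinom(n, 1L, pr$frac_disabled),
        x_low_ses = stats::rbinom(n, 1L, p_ses)
      )
    }
  )
}

#' Enumerate the 16 risk-factor cells of a tract population
#'
#' The analytic counterpart of [generate_individuals()]: instead of
#' sampling residents, returns the sixteen possible indicator combinations
#' with expected counts `weight = n_residents * prod(marginal
#' probabilities)` under the independence assumption. Weights sum to
#' `n_residents` exactly, so the cascade can run on expected counts with no
#' sampling noise.
#'
#' @inheritParams generate_individuals
#' @return A tibble with `tract_id`, the four indicator columns and
#'   `weight`; 16 rows per tract.
#' @examples
#' tiberias_tracts() |> enumerate_cells()
#' @export
enumerate_cells <- function(profiles, ses_mode = "all_one", ses_rate = NULL) {
  profiles <- validate_tract_profiles(profiles)
  grid <- tidyr::expand_grid(x_age = 0:1, x_female = 0:1,
                             x_disabled = 0:1, x_low_ses = 0:1)
  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    pr <- profiles[i, ]
    p <- c(pr$frac_over_65, pr$frac_female, pr$frac_disabled,
           ses_probability(pr, ses_mode, ses_rate))
    w <- apply(grid, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
    dplyr::bind_cols(tract_id = pr$tract_id, grid,
                     weight = pr$n_residents * w)
  })
}
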