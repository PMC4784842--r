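zero_pop <- function(n, tract = "t") {
  tibble::tibble(tract_id = tract, x_age = 0L, x_female = 0L,
                 x_disabled = 0L, x_low_ses = 0L)[rep(1, n), ]
}

test_that("the logistic model reproduces the baseline rate and the worked equation", {
  d <- coefficient_set("death")
  b0 <- baseline_intercept(0.10)
  # no risk factors: the HAZUS collapse fatality rate comes back exactly
  expect_equal(injury_probability(zero_pop(1), b0, d), 0.10)
  # all four factors present: p = 1 / (1 + e^-0.455)
  all_one <- tibble::tibble(x_age = 1, x_female = 1, x_disabled = 1, x_low_ses = 1)
  expect_equal(injury_probability(all_one, b0, d), plogis(0.455), tolerance = 1e-3)
  expect_equal(injury_probability(all_one, b0, d), 0.612, tolerance = 1e-3)
  # non-binary indicators are rejected
  expect_error(
    injury_probability(tibble::tibble(x_age = 0.5, x_female = 0,
                                      x_disabled = 0, x_low_ses = 0), b0, d),
    "0 or 1"
  )
})

test_that("probability is monotone in each risk factor for non-negative coefficients", {
  set.seed(9)
  for (i in 1:20) {
    cf <- coefficient_set("death", source = "custom", betas = runif(4, 0, 2))
    b0 <- baseline_intercept(runif(1, 0.01, 0.5))
    base <- tidyr::expand_grid(x_age = 0:1, x_female = 0:1,
                               x_disabled = 0:1, x_low_ses = 0:1)
    p <- injury_probability(base, b0, cf)
    for (col in c("x_age", "x_female", "x_disabled", "x_low_ses")) {
      flipped <- base
      flipped[[col]] <- 1L
      expect_true(all(injury_probability(flipped, b0, cf) >= p - 1e-15))
    }
  }
})

test_that("expected counts round the sum of probabilities and respect the pool size", {
  expect_identical(expected_count(rep(0.1, 100)), 10L)
  expect_identical(expected_count(numeric(0)), 0L)
  expect_identical(expected_count(c(0.5, 0.5, 0.5)), 2L)  # half away from zero
  expect_identical(expected_count(c(0.5, 0.5, 0.5), rounding = "floor"), 1L)
  expect_identical(expected_count(rep(1, 5)), 5L)
  expect_error(expected_count(c(0.2, 1.3)), "probabilities")
})

test_that("tract 11's fatal-step expectation matches the analytic enumeration", {
  tr <- tiberias_tracts()
  cells <- enumerate_cells(tr[tr$tract_id == "11", ])
  p <- injury_probability(cells, baseline_intercept(0.10), coefficient_set("death"))
  # frozen from an independent cell-by-cell enumeration of the logistic model
  expect_equal(sum(cells$weight * p), 1481.543, tolerance = 1e-3)
})

test_that("a risk-free population reproduces the closed-form cascade numbers", {
  cfg <- scenario_config()
  tally <- run_cascade(zero_pop(1000), cfg)
  got <- setNames(tally$count, tally$severity)
  # 10% fatal, then 5% / 20% / 40% of each successive remainder
  expect_identical(got, c(fatal = 100L, severe = 45L, moderate = 171L,
                          light = 274L, uninjured = 410L))
  expect_equal(tally$fraction, c(0.1, 0.045, 0.171, 0.274, 0.410))

  # same numbers from the cell-weighted route with null coefficients
  null <- coefficient_set("death", source = "custom", betas = rep(0, 4))
  cells <- enumerate_cells(
    tibble::tibble(tract_id = "t", n_residents = 10000, frac_over_65 = 0.2,
                   frac_female = 0.5, frac_disabled = 0.1),
    ses_mode = "all_one"
  )
  cfg0 <- scenario_config(death_coeffs = null, injury_coeffs = null)
  t0 <- run_cascade(cells, cfg0)
  expect_identical(setNames(t0$count, t0$severity),
                   c(fatal = 1000L, severe = 450L, moderate = 1710L,
                     light = 2736L, uninjured = 4104L))
})

test_that("zero-rate damage states produce structural-zero severities", {
  cfg <- scenario_config(damage_state = "slight")
  pop <- zero_pop(500)
  tally <- run_cascade(pop, cfg)
  got <- setNames(tally$count, tally$severity)
  expect_identical(got[["fatal"]], 0L)
  expect_identical(got[["severe"]], 0L)
  expect_identical(got[["light"]], as.integer(round(500 * 0.0005)))
  expect_identical(sum(tally$count), 500L)
})

test_that("residents are conserved across severities for random profiles", {
  set.seed(31)
  for (i in 1:100) {
    pr <- random_profile(i)
    cfg <- scenario_config(
      damage_state = sample(damage_states(), 1),
      population = sample(c("cells", "sampled"), 1),
      ses_mode = sample(c("all_one", "all_zero"), 1),
      seed = i
    )
    est <- estimate_casualties(pr, cfg)
    expect_identical(sum(est$tally$count), as.integer(pr$n_residents))
    expect_true(all(est$tally$count >= 0))
    expect_equal(sum(est$tally$fraction), 1, tolerance = 1e-9)
  }
})

test_that("the cascade matches a brute-force transcription on random populations", {
  set.seed(77)
  rt <- casualty_rates()
  for (i in 1:15) {
    n <- sample(30:300, 1)
    X <- matrix(rbinom(4 * n, 1, runif(4)), ncol = 4,
                dimnames = list(NULL, c("x_age", "x_female", "x_disabled", "x_low_ses")))
    pop <- dplyr::bind_cols(tract_id = "t", tibble::as_tibble(X))
    state <- sample(damage_states(), 1)
    cfg <- scenario_config(damage_state = state)
    got <- run_cascade(pop, cfg)
    ref <- oracle_cascade_individuals(X, state, rt, death_betas(), injury_betas())
    expect_identical(setNames(got$count, got$severity), ref)
  }
})

test_that("within each step every removed resident is at least as likely as any retained one", {
  # one high-risk block and one risk-free block: the fatal step must take
  # all high-risk residents before any risk-free one
  pop <- dplyr::bind_rows(
    tibble::tibble(tract_id = "t", x_age = 1L, x_female = 1L,
                   x_disabled = 1L, x_low_ses = 1L)[rep(1, 40), ],
    zero_pop(160)
  )
  cfg <- scenario_config()
  tally <- run_cascade(pop, cfg)
  d <- coefficient_set("death")
  p_hi <- injury_probability(pop[1, ], baseline_intercept(0.10), d)
  n_fatal <- tally$count[tally$severity == "fatal"]
  expect_identical(n_fatal, as.integer(round(40 * p_hi + 160 * 0.10)))
  expect_gte(n_fatal, 40L)  # removal order: all 40 high-risk residents go first
  # the severe step then sees a pool whose first members are risk-free, so
  # its count must match the oracle on the depleted pool
  ref <- oracle_cascade_individuals(
    as.matrix(pop[, c("x_age", "x_female", "x_disabled", "x_low_ses")]),
    "complete_collapse", casualty_rates(), death_betas(), injury_betas()
  )
  expect_identical(setNames(tally$count, tally$severity), ref)
})

test_that("sampled and cell-weighted cascades agree within binomial noise", {
  pr <- tibble::tibble(tract_id = "t", n_residents = 2000, frac_over_65 = 0.1,
                       frac_female = 0.5, frac_disabled = 0.1)
  cells <- enumerate_cells(pr)
  ref <- oracle_cascade_cells(cells, "complete_collapse", casualty_rates(),
                              death_betas(), injury_betas())
  cfg_cells <- scenario_config(population = "cells")
  cell_tally <- run_cascade(cells, cfg_cells)
  for (seed in 0:9) {
    est <- estimate_casualties(pr, scenario_config(population = "sampled", seed = seed))
    for (s in c("fatal", "severe", "moderate", "light")) {
      bound <- 3 * sqrt(ref[[s]][["V"]]) + 1  # +1 for count rounding
      got <- est$tally$count[est$tally$severity == s]
      want <- cell_tally$count[cell_tally$severity == s]
      expect_lt(abs(got - want), bound)
    }
  }
})

test_that("tract damage states must be resolvable", {
  pop <- zero_pop(10, tract = "t9")
  cfg <- scenario_config(damage_state = c(t1 = "slight"))
  expect_error(run_cascade(pop, cfg), "t9")
  expect_error(scenario_config(damage_state = "apocalyptic"), "damage_state")
})

test_that("city aggregation is resident-weighted and carries the HAZUS reference", {
  est <- estimate_casualties(tiberias_tracts(), scenario_config())
  city <- est$city
  expect_equal(sum(city$count), 42079)
  expect_equal(sum(city$pct), 100, tolerance = 1e-9)
  ref <- setNames(city$hazus_pct, city$severity)
  expect_identical(ref, c(fatal = 10, severe = 5, moderate = 20, light = 40,
                          uninjured = 25))
  # a single tract aggregates to its own fractions
  one <- estimate_casualties(tiberias_tracts()[1, ], scenario_config())
  expect_equal(one$city$pct, 100 * one$tally$fraction, tolerance = 1e-9)
  # percentage-point deltas
  cmp <- compare_to_hazus(est)
  expect_equal(cmp$delta_pct_points, city$pct - city$hazus_pct)
  expect_error(compare_to_hazus(dplyr::select(city, -pct)), "pct")
})
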