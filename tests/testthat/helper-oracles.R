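# Independent oracles: direct transcriptions of the textbook formulas,
# sharing no code with the package implementation.

# DerSimonian-Laird pooling of odds ratios, from printed OR + 95% CI
dl_oracle <- function(or, lo, hi) {
  y <- log(or)
  se <- (log(hi) - log(lo)) / (2 * 1.96)
  w <- 1 / se^2
  y_fixed <- sum(w * y) / sum(w)
  q <- sum(w * (y - y_fixed)^2)
  k <- length(y)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  mu <- sum(ws * y) / sum(ws)
  se_mu <- 1 / sqrt(sum(ws))
  list(
    log_or = mu, se_log_or = se_mu, tau_sq = tau2, q_stat = q,
    pooled_or = exp(mu),
    ci_low = exp(mu - 1.96 * se_mu), ci_high = exp(mu + 1.96 * se_mu),
    y_fixed = y_fixed
  )
}

# Brute-force severity cascade on enumeration cells; returns per-step
# expectation E and variance term V = sum w p (1 - p), plus leftover weight.
oracle_cascade_cells <- function(cells, state, rate_tbl, bd, bi) {
  w <- cells$weight
  X <- as.matrix(cells[, c("x_age", "x_female", "x_disabled", "x_low_ses")])
  out <- list()
  for (s in c("fatal", "severe", "moderate", "light")) {
    r <- rate_tbl$rate[rate_tbl$damage_state == state & rate_tbl$severity == s]
    b <- if (s == "fatal") bd else bi
    lp <- if (r == 0) rep(-Inf, nrow(X)) else log(r / (1 - r)) + as.vector(X %*% b)
    p <- 1 / (1 + exp(-lp))
    e <- sum(w * p)
    out[[s]] <- c(E = e, V = sum(w * p * (1 - p)))
    rem <- e
    for (i in order(-p, seq_along(p))) {
      take <- min(w[i], rem)
      w[i] <- w[i] - take
      rem <- rem - take
      if (rem <= 1e-12) break
    }
  }
  out$uninjured <- sum(w)
  out
}

# Brute-force cascade on an indicator matrix of individuals; returns the
# integer counts per severity plus uninjured.
oracle_cascade_individuals <- function(X, state, rate_tbl, bd, bi) {
  counts <- integer(0)
  for (s in c("fatal", "severe", "moderate", "light")) {
    r <- rate_tbl$rate[rate_tbl$damage_state == state & rate_tbl$severity == s]
    b <- if (s == "fatal") bd else bi
    lp <- if (r == 0) rep(-Inf, nrow(X)) else log(r / (1 - r)) + as.vector(X %*% b)
    p <- 1 / (1 + exp(-lp))
    n_s <- as.integer(min(floor(sum(p) + 0.5), length(p)))
    if (n_s > 0) {
      drop <- order(-p, seq_along(p))[seq_len(n_s)]
      X <- X[-drop, , drop = FALSE]
    }
    counts[s] <- n_s
  }
  counts["uninjured"] <- nrow(X)
  counts
}

# canonical coefficient vectors, in indicator order
death_betas <- function() c(1.073, 0.182, 0.609, 0.788)
injury_betas <- function() c(log(1.3), log(1.7), 0.609, 0.788)

# a random tract profile for property-style tests
random_profile <- function(id, n_max = 500) {
  tibble::tibble(
    tract_id = as.character(id),
    n_residents = sample(20:n_max, 1),
    frac_over_65 = runif(1),
    frac_female = runif(1),
    frac_disabled = runif(1)
  )
}
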