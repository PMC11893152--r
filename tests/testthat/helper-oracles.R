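# Independent oracles used by the tests. These deliberately re-derive the
# quantities from first principles (explicit risk-set loops, grid search)
# and never call the package's fitting path.

# Breslow log partial likelihood by direct risk-set enumeration.
oracle_breslow_loglik <- function(time, event, x, beta) {
  eta <- as.numeric(as.matrix(x) %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Single-covariate Cox coefficient by brute-force grid search of the
# Breslow partial likelihood over beta in [-5, 5], step 1e-4.
oracle_grid_cox <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(b) oracle_breslow_loglik(time, event, x, b),
               numeric(1))
  grid[which.max(ll)]
}

# Fixed tiny survival cohorts (n <= 8, distinct times, binary covariate)
# for the grid-search equivalence checks.
tiny_cohorts <- function() {
  list(
    list(time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 0, 1, 1, 0),
         x = c(1, 0, 1, 0, 1, 0)),
    list(time = c(2.5, 1.2, 4.8, 3.3, 0.7, 5.9), event = c(1, 0, 1, 1, 1, 0),
         x = c(0, 1, 1, 0, 1, 0)),
    list(time = c(1, 2, 3, 4, 5, 6, 7, 8), event = c(1, 1, 1, 0, 1, 0, 1, 0),
         x = c(1, 1, 0, 0, 1, 0, 0, 1)),
    list(time = c(3.1, 1.4, 2.2, 5.5, 4.4), event = c(1, 1, 1, 1, 1),
         x = c(1, 0, 1, 0, 0)),
    list(time = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5), event = c(0, 1, 1, 1, 0, 1, 1),
         x = c(1, 0, 0, 1, 1, 0, 1))
  )
}

# Small two-score cohort used across analysis tests.
small_test_cohort <- function(n = 4000, seed = 42, ...) {
  generate_cohort(sim_config(n = n, seed = seed, ...))
}
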