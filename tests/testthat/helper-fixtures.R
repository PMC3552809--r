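# shared fixture builders; everything generated in code

# independent evaluation of the expected-count product formula by plain
# double loops (oracle for the vectorised implementation)
oracle_mu <- function(grid, h, p, q) {
  yrs <- grid_years(grid)
  n <- length(yrs)
  mu <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j == i) {
        mu[i, j] <- 0.5 * h[i] * p[i]
      } else {
        surv <- 1
        for (k in i:(j - 1)) surv <- surv * (1 - p[k] - q[k])
        mu[i, j] <- h[i] * surv * p[j]
      }
    }
  }
  mu
}

# random valid (grid, h, p, q) instance
random_instance <- function(n = NULL, full_obs = TRUE) {
  if (is.null(n)) n <- sample(2:8, 1)
  first <- 2000L
  obs <- if (full_obs) first else first + sample.int(n - 1L, 1L)
  g <- year_grid(first, obs, first + n - 1L)
  p <- runif(n, 0.01, 0.5)
  q <- runif(n, 0.01, 1 - p - 0.05)
  list(grid = g, h = runif(n, 1, 5000), p = p, q = q)
}

# small well-identified simulated dataset with pre-observation years whose
# truth satisfies the estimator's assumptions: pre-obs p follows the
# flat-plus-ramp rule and window p is geometric (log-linear, i.e. zero
# log-scale roughness, the ridge-selection optimum)
toy_truth <- function(n = 10, n_pre = 3, h = 1000, p0 = 0.12, growth = 1.1,
                      mortality = 0.02, cessation = 0.04, flat = 0.01) {
  first <- 2001L
  g <- year_grid(first, first + n_pre, first + n - 1L)
  lv <- leaving_schedule(g, mortality = mortality, cessation = cessation)
  rule <- pre_obs_rule(flat_value = flat)
  yrs <- grid_years(g)
  nw <- sum(yrs >= g$first_obs_year)
  p <- numeric(n)
  p[yrs >= g$first_obs_year] <- p0 * growth^(0:(nw - 1))
  if (n_pre > 0)
    p[yrs < g$first_obs_year] <- apply_pre_obs_rule(rule, p0, g)
  list(grid = g, params = parameter_vector(g, h, p), leaving = lv,
       rule = rule)
}

simulate_counts_from <- function(truth, seed) {
  rec <- simulate_careers(sim_spec(truth$grid, truth$params, truth$leaving,
                                   seed = seed))
  aggregate_records(rec, truth$grid)
}
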