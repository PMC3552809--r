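test_that("expected counts follow the survival-product formula", {
  # two intervening years at p = 0.01, q = 0.05: mu = 1000 * 0.94^2 * 0.01
  g <- year_grid(2000, 2000, 2002)
  pars <- parameter_vector(g, h = c(1000, 0, 0), p = 0.01)
  lv <- leaving_schedule(g, mortality = 0.01, cessation = 0.04)
  mu <- expected_counts(pars, lv)
  expect_equal(mu[1, 3], 8.836, tolerance = 1e-12)
  # same-year cell carries the half-year exposure weight
  g1 <- year_grid(2005, 2005, 2005)
  mu1 <- expected_counts(parameter_vector(g1, 100, 0.2),
                         leaving_schedule(g1, 0.01, 0.04))
  expect_equal(mu1[1, 1], 10)
  # zero immigration gives zero expectation everywhere
  mu0 <- expected_counts(parameter_vector(g, 0, 0.2), lv)
  expect_true(all(mu0 == 0))
})

test_that("expected counts match a double-loop oracle on random instances", {
  set.seed(401)
  for (rep in 1:25) {
    inst <- random_instance()
    mu <- expected_counts(parameter_vector(inst$grid, inst$h, inst$p),
                          leaving_schedule(inst$grid, inst$q, 0))
    ref <- oracle_mu(inst$grid, inst$h, inst$p, inst$q)
    expect_equal(unclass(mu), ref, tolerance = 1e-13, ignore_attr = TRUE)
  }
})

test_that("invalid survival mass is rejected, not clamped", {
  g <- year_grid(2000, 2000, 2002)
  pars <- parameter_vector(g, h = 100, p = 0.6)
  lv <- leaving_schedule(g, mortality = 0.2, cessation = 0.3)  # p + q = 1.1
  expect_error(expected_counts(pars, lv), "survival factor negative")
})

test_that("cohort mass accounting: sum_j mu_ij / h_i stays in [0, 1]", {
  set.seed(402)
  for (rep in 1:20) {
    inst <- random_instance()
    mu <- expected_counts(parameter_vector(inst$grid, inst$h, inst$p),
                          leaving_schedule(inst$grid, inst$q, 0))
    frac <- rowSums(mu) / inst$h
    expect_true(all(frac >= 0 & frac <= 1 + 1e-12))
    # survival product is non-increasing in lag
    n <- n_years(inst$grid)
    for (i in seq_len(n)) {
      surv <- cumprod(c(1, (1 - inst$p - inst$q)[i:n]))
      expect_true(all(surv >= 0 & surv <= 1) && all(diff(surv) <= 1e-15))
    }
  }
})

test_that("log-likelihood reproduces hand-computed values", {
  g <- year_grid(2000, 2000, 2000)
  lv <- leaving_schedule(g, 0.01, 0.04)
  cm <- count_matrix(g, matrix(3, 1, 1))
  mu <- expected_counts(parameter_vector(g, h = 20, p = 0.2), lv)  # mu = 2
  expect_equal(log_likelihood(cm, mu), 3 * log(2) - 2, tolerance = 1e-12)
  # empty data limit: log L = -sum(mu)
  cm0 <- count_matrix(g, matrix(0, 1, 1))
  expect_equal(log_likelihood(cm0, mu), -2)
})

test_that("likelihood sums only over the observation window", {
  g <- year_grid(2000, 2003, 2005)
  lv <- leaving_schedule(g, 0.01, 0.04)
  pars <- parameter_vector(g, h = 500, p = 0.15)
  mu <- expected_counts(pars, lv)
  n <- n_years(g)
  cm0 <- count_matrix(g, matrix(0, n, n))
  cells <- expand.grid(i = 1:n, j = 1:n)
  cells <- cells[cells$j >= cells$i & cells$j >= 4, ]
  expect_equal(log_likelihood(cm0, mu), -sum(mu[as.matrix(cells)]))
})

test_that("saturated expectations maximise the cellwise likelihood", {
  set.seed(403)
  inst <- random_instance(n = 4)
  g <- inst$grid
  lv <- leaving_schedule(g, inst$q, 0)
  mu <- expected_counts(parameter_vector(g, inst$h, inst$p), lv)
  n <- n_years(g)
  N <- matrix(0, n, n)
  N[upper.tri(N, diag = TRUE)] <- rpois(sum(upper.tri(N, diag = TRUE)),
                                        mu[upper.tri(mu, diag = TRUE)])
  cm <- count_matrix(g, N)
  sat <- mu; sat[] <- 0
  sat[upper.tri(sat, diag = TRUE)] <- N[upper.tri(N, diag = TRUE)]
  ll_sat <- sum(ifelse(N > 0, N * log(N) - N, 0)[upper.tri(N, diag = TRUE)])
  expect_equal(log_likelihood(cm, sat), ll_sat, tolerance = 1e-12)
  # moving every expectation away from the data strictly decreases it
  doubled <- sat; doubled[] <- 2 * sat + 0.5 * (sat == 0)
  doubled[lower.tri(doubled)] <- 0
  expect_lt(log_likelihood(cm, doubled), log_likelihood(cm, sat))
})

test_that("zero count with zero expectation contributes nothing", {
  g <- year_grid(2000, 2000, 2001)
  lv <- leaving_schedule(g, 0.01, 0.04)
  mu <- expected_counts(parameter_vector(g, c(100, 0), c(0.2, 0.2)), lv)
  cm <- count_matrix(g, matrix(c(5, 0, 0, 0), 2, 2, byrow = TRUE))
  expect_true(is.finite(log_likelihood(cm, mu)))
  # positive count on a zero expectation is a hard error naming the cell
  cm2 <- count_matrix(g, matrix(c(5, 0, 0, 3), 2, 2, byrow = TRUE))
  expect_error(log_likelihood(cm2, mu), "onset 2001")
})

test_that("count matrices validate structure and build from long format", {
  g <- year_grid(2000, 2001, 2003)
  n <- 4
  m <- matrix(0, n, n)
  m[1, 2] <- 3
  expect_s3_class(count_matrix(g, m), "count_matrix")
  bad <- m; bad[3, 1] <- 1
  expect_error(count_matrix(g, bad), "before onset")
  expect_error(count_matrix(g, m - 0.5), "non-negative integers")
  long <- data.frame(onset_year = c(2000, 2000, 2002),
                     treatment_year = c(2001, 2001, 2002),
                     count = c(1, 1, 4))
  cm <- count_matrix(g, long)
  expect_equal(cm[1, 2], 2)
  expect_equal(cm[3, 3], 4)
})

test_that("count and expected tables round-trip through delimited text", {
  set.seed(404)
  inst <- random_instance(n = 5)
  g <- inst$grid
  lv <- leaving_schedule(g, inst$q, 0)
  mu <- expected_counts(parameter_vector(g, inst$h, inst$p), lv)
  n <- n_years(g)
  N <- matrix(0, n, n)
  N[upper.tri(N, diag = TRUE)] <- rpois(sum(upper.tri(N, diag = TRUE)), 5)
  cm <- count_matrix(g, N)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_counts(cm, f1)
  write_expected(mu, f2)
  expect_equal(unclass(read_counts(f1, g)), unclass(cm), ignore_attr = TRUE)
  expect_equal(unclass(read_expected(f2, g)), unclass(mu),
               tolerance = 1e-12, ignore_attr = TRUE)
  unlink(c(f1, f2))
})
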