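test_that("record loading filters, aggregates and logs drops", {
  g <- year_grid(1971, 1991, 2006)
  df <- data.frame(
    onset_year = c(1985, 1985, 1990, 1960, 1985, 1994),
    treatment_year = c(1992, 1992, 1991, 1992, 1989, 2007),
    stratum = c("inject", "other", "inject", "inject", "other", "other"))
  lr <- load_records(df, g)
  expect_equal(lr$pooled[year_index(g, 1985), year_index(g, 1992)], 2)
  expect_equal(lr$pooled[year_index(g, 1990), year_index(g, 1991)], 1)
  expect_equal(sum(unclass(lr$pooled)), 3)
  expect_setequal(lr$dropped$reason,
                  c("onset_outside_grid", "treatment_outside_window"))
  # causality violations abort with row numbers
  bad <- data.frame(onset_year = c(1990, 1995), treatment_year = c(1989, 1996))
  expect_error(load_records(bad, g), "row\\(s\\): 1")
  # malformed years are dropped, not fatal
  msg <- data.frame(onset_year = c("1985", "19x5"), treatment_year = c("1992", "1993"))
  lr2 <- load_records(msg, g)
  expect_equal(nrow(lr2$records), 1)
  expect_true("malformed_year" %in% lr2$dropped$reason)
})

test_that("stratified loading accounts for missing strata", {
  g <- year_grid(1980, 1990, 1999)
  df <- data.frame(
    onset_year = rep(1985, 10),
    treatment_year = rep(1995, 10),
    stratum = c(rep("inject", 4), rep("other", 3), NA, NA, ""))
  lr <- load_records(df, g)
  expect_equal(sum(unclass(lr$pooled)), 10)
  expect_equal(sum(unclass(lr$strata$inject)), 4)
  expect_equal(sum(unclass(lr$strata$other)), 3)
  expect_equal(sum(unclass(lr$strata$inject)) + sum(unclass(lr$strata$other)),
               sum(unclass(lr$pooled)) - 3)
})

test_that("age columns act as row filters only", {
  g <- year_grid(1980, 1990, 1999)
  df <- data.frame(onset_year = rep(1985, 4), treatment_year = rep(1995, 4),
                   onset_age = c(9, 20, 44, 45),
                   treatment_age = c(30, 30, 30, 30))
  lr <- load_records(df, g, onset_age_range = c(10, 44))
  expect_equal(nrow(lr$records), 2)
  lr2 <- load_records(df, g)
  expect_equal(nrow(lr2$records), 4)
})

test_that("records written to text reload identically", {
  truth <- toy_truth(n = 8, n_pre = 2, h = 300)
  rec <- observed_records(simulate_careers(
    sim_spec(truth$grid, truth$params, truth$leaving, seed = 71)))
  f <- tempfile(fileext = ".tsv")
  write_records(rec, f)
  lr <- load_records(f, truth$grid)
  expect_equal(unclass(lr$pooled), unclass(aggregate_records(rec, truth$grid)),
               ignore_attr = TRUE)
  unlink(f)
})

test_that("rate conversion is a plain ratio per 1,000", {
  expect_equal(to_rates(1500, 1e6), 1.5)
  expect_equal(to_rates(0, 123456), 0)
  expect_equal(to_rates(c(100, 100), c(1e5, 2e5)), c(1, 0.5))
  expect_error(to_rates(c(1, 2), 1e5), "denominators missing")
  expect_error(to_rates(1, -5), "positive")
})

test_that("goodness of fit is zero at saturation and flags empty cohorts", {
  truth <- toy_truth(n = 8, n_pre = 2, h = 500)
  cnt <- simulate_counts_from(truth, seed = 72)
  g <- truth$grid
  # a saturated expectation equal to the data has zero deviance everywhere
  n <- n_years(g)
  sat <- matrix(0, n, n)
  sat[upper.tri(sat, diag = TRUE)] <- unclass(cnt)[upper.tri(sat, diag = TRUE)]
  sat <- structure(sat, grid = g, class = c("expected_matrix", "matrix"))
  gof_sat <- gof_cohort_curves(cnt, sat)
  expect_equal(gof_sat$deviance$deviance, rep(0, n))
  expect_equal(gof_sat$mean_cell_deviance, 0)
  # fitted model: per-cohort observed and expected series align by year
  fit <- backcalc(cnt, truth$leaving, rule = truth$rule)
  gof <- gof_cohort_curves(cnt, fitted(fit))
  expect_equal(sum(gof$curves$observed), sum(unclass(cnt)))
  expect_true(all(gof$deviance$deviance >= 0))
  # an all-zero cohort with zero expectation is marked empty
  m0 <- matrix(0, n, n); m0[n, n] <- 0
  cnt0 <- count_matrix(g, m0)
  mu0 <- expected_counts(parameter_vector(g, c(rep(100, n - 1), 0), 0.2),
                         truth$leaving)
  gof0 <- gof_cohort_curves(cnt0, mu0)
  expect_true(gof0$deviance$empty[n])
})

test_that("lag distributions normalise within eligible cells", {
  truth <- toy_truth(n = 9, n_pre = 3, h = 800)
  cnt <- simulate_counts_from(truth, seed = 73)
  g <- truth$grid
  fit <- backcalc(cnt, truth$leaving, rule = truth$rule)
  ld_obs <- lag_distributions(cnt)
  ld_exp <- lag_distributions(fitted(fit))
  for (ld in list(ld_obs, ld_exp)) {
    sums <- tapply(ld$mass, ld$onset_year, sum)
    sums <- sums[!is.na(sums)]
    expect_true(all(abs(sums - 1) < 1e-12))
  }
  # the default cutoff excludes the final grid year
  expect_true(all(ld_obs$onset_year + ld_obs$lag < g$last_year))
  # expected version equals mu normalised over eligible lags
  i <- year_index(g, g$first_obs_year)
  mu <- fitted(fit)
  elig <- i:(n_years(g) - 1)
  manual <- mu[i, elig] / sum(mu[i, elig])
  got <- ld_exp$mass[ld_exp$onset_year == g$first_obs_year]
  expect_equal(unname(got), unname(manual), tolerance = 1e-12)
  # single-cell cohort collapses to a point mass
  n <- n_years(g)
  m1 <- matrix(0, n, n); m1[n - 1, n - 1] <- 7
  ld1 <- lag_distributions(count_matrix(g, m1),
                           cutoff_year = g$last_year)
  expect_equal(ld1$mass[ld1$onset_year == grid_years(g)[n - 1] & ld1$lag == 0], 1)
  # cohorts without eligible mass are flagged
  expect_true(length(attr(ld1, "empty_cohorts")) > 0)
})

test_that("sensitivity runs fit all scenarios and rank them by recovery", {
  # generated under the default scenario (unmodified mortality, cessation
  # 0.04) on a reduced-scale epidemic
  spec <- synthetic_epidemic_spec(h_scale = 0.3, seed = 74)
  cnt <- aggregate_records(simulate_careers(spec))
  g <- spec$grid
  rule <- pre_obs_rule(flat_until = 1981)
  sens <- run_sensitivity(cnt, mortality = mortality_curve(g), rule = rule)
  expect_length(sens$fits, 4)
  expect_equal(nrow(sens$table), 4 * n_years(g))
  # the scenario matching the generating q recovers the truth best
  mse <- vapply(sens$fits, function(f)
    mean((f$params$h - spec$params$h)^2), 0)
  expect_equal(names(which.min(mse)), "cess0.04_offset0.00")
  # total incidence is monotone in the scenario's total leaving rate
  tot <- vapply(sens$fits, function(f) sum(f$params$h), 0)
  lev <- vapply(sensitivity_scenarios(), function(s)
    s$cessation + s$mortality_offset, 0)
  expect_equal(order(tot), order(lev[names(tot)]))
})

test_that("population denominators are synthetic but well-formed", {
  g <- year_grid(1971, 1991, 2006)
  pop <- synthetic_population(g)
  expect_length(pop, n_years(g))
  expect_true(all(pop > 0))
  expect_true(all(diff(pop) >= 0))
})
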