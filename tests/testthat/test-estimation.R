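test_that("pre-observation rule fills flat segment and linear ramp", {
  g <- year_grid(1971, 1991, 2006)
  rule <- pre_obs_rule(flat_value = 0.01, flat_until = 1981)
  p_pre <- apply_pre_obs_rule(rule, p_link = 0.11, g)
  expect_equal(unname(p_pre["1986"]), 0.06)          # ramp midpoint
  expect_equal(unname(p_pre["1981"]), 0.01)          # flat regardless of link
  expect_true(all(p_pre[as.character(1971:1981)] == 0.01))
  expect_equal(unname(p_pre["1990"]), 0.01 + 0.9 * 0.10)
  # degenerate ramp: link value equal to the flat level
  expect_equal(unname(apply_pre_obs_rule(rule, 0.01, g)), rep(0.01, 20))
  # default flat_until resolves to the midpoint of the pre-observation span
  p_def <- apply_pre_obs_rule(pre_obs_rule(), 0.11, g)
  expect_equal(unname(p_def["1981"]), 0.01)
  expect_gt(unname(p_def["1982"]), 0.01)
})

test_that("single-year fit with known p recovers the closed form 2N/p", {
  g <- year_grid(2000, 2000, 2000)
  lv <- leaving_schedule(g, 0.01, 0.04)
  fit <- backcalc(count_matrix(g, matrix(10, 1, 1)), lv, fixed_p = 0.1)
  expect_equal(unname(fit$params$h), 2 * 10 / 0.1, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("the likelihood ridge is exactly flat and ridge_shift tracks it", {
  truth <- toy_truth(n = 9, n_pre = 3)
  cnt <- simulate_counts_from(truth, seed = 31)
  fit <- backcalc(cnt, truth$leaving, rule = truth$rule, identify = "none")
  for (cc in c(0.9, 1.15, 1.4)) {
    sh <- ridge_shift(fit, cc)
    expect_equal(sh$loglik, fit$loglik, tolerance = 1e-9)
    # parameters genuinely move along the family
    expect_false(isTRUE(all.equal(sh$params$h, fit$params$h, tolerance = 1e-3)))
    # observable expectations are untouched
    cells <- which(upper.tri(fit$mu_hat, diag = TRUE), arr.ind = TRUE)
    keep <- grid_years(truth$grid)[cells[, 2]] >= truth$grid$first_obs_year
    expect_equal(sh$mu_hat[cells[keep, ]], fit$mu_hat[cells[keep, ]],
                 tolerance = 1e-8)
  }
  expect_error(ridge_shift(fit, 1e-4), "feasible range")
})

test_that("smooth identification makes the fit start-independent", {
  truth <- toy_truth(n = 10, n_pre = 3, h = 1200)
  cnt <- simulate_counts_from(truth, seed = 32)
  fit0 <- backcalc(cnt, truth$leaving, rule = truth$rule)
  expect_identical(fit0$identify, "smooth")
  set.seed(33)
  n <- n_years(truth$grid)
  nw <- length(obs_years(truth$grid))
  for (k in 1:4) {
    st <- list(h = fit0$params$h * exp(runif(n, -1, 1)),
               p = pmin(pmax(fit0$params$p[(n - nw + 1):n] *
                               exp(runif(nw, -0.7, 0.7)), 0.02), 0.6))
    fk <- backcalc(cnt, truth$leaving, rule = truth$rule, start = st)
    expect_equal(fk$loglik, fit0$loglik, tolerance = 1e-6)
    expect_equal(fk$params$h, fit0$params$h, tolerance = 0.01)
    expect_equal(fk$params$p, fit0$params$p, tolerance = 0.01)
  }
})

test_that("smooth identification recovers a self-consistent truth", {
  # tolerances sized for this short 9-window-year toy; the acceptance suite
  # checks the tighter bounds on the full 36-year design
  truth <- toy_truth(n = 12, n_pre = 3, h = 2000)
  cnt <- simulate_counts_from(truth, seed = 34)
  fit <- backcalc(cnt, truth$leaving, rule = truth$rule)
  well <- fit$cohort_observed >= 300
  expect_true(sum(well) >= 5)
  hrel <- abs(fit$params$h - truth$params$h) / truth$params$h
  expect_lt(max(hrel[well]), 0.15)
  expect_lt(max(abs(fit$params$p - truth$params$p)[well]), 0.035)
})

test_that("scaling every count scales incidence and leaves p alone", {
  truth <- toy_truth(n = 8, n_pre = 2, h = 900)
  cnt <- simulate_counts_from(truth, seed = 35)
  g <- truth$grid
  fit1 <- backcalc(cnt, truth$leaving, rule = truth$rule)
  cnt4 <- count_matrix(g, unclass(cnt) * 4L)
  fit4 <- backcalc(cnt4, truth$leaving, rule = truth$rule)
  expect_equal(fit4$params$h / fit1$params$h, rep(4, n_years(g)),
               tolerance = 0.02)
  expect_equal(fit4$params$p, fit1$params$p, tolerance = 0.01)
})

test_that("two-stage linkage approximates the simultaneous fit", {
  truth <- toy_truth(n = 9, n_pre = 3, h = 1500)
  cnt <- simulate_counts_from(truth, seed = 36)
  f1 <- backcalc(cnt, truth$leaving, rule = truth$rule)
  f2 <- backcalc(cnt, truth$leaving, rule = truth$rule, link = "two_stage")
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-3)
  expect_equal(f2$params$p, f1$params$p, tolerance = 0.05)
})

test_that("degenerate inputs are rejected and weak cohorts flagged", {
  g <- year_grid(2000, 2002, 2006)
  lv <- leaving_schedule(g, 0.02, 0.04)
  n <- n_years(g)
  expect_error(backcalc(count_matrix(g, matrix(0, n, n)), lv),
               "all observed counts are zero")
  truth <- toy_truth(n = 8, n_pre = 2, h = 600)
  cnt <- simulate_counts_from(truth, seed = 37)
  fit <- backcalc(cnt, truth$leaving, rule = truth$rule)
  s <- summary(fit)
  # final onset year rests on a single observable cell: flagged
  expect_true(s$table$weak[nrow(s$table)] ||
                s$table$n_cells[nrow(s$table)] <= 2)
  expect_error(backcalc(cnt, truth$leaving, rule = truth$rule, fixed_p = 1.2),
               "fixed_p")
  expect_error(backcalc(cnt, truth$leaving, rule = truth$rule,
                        start = list(p = c(0.1, 0.2))), "start\\$p")
})

test_that("fit accessors are mutually consistent", {
  truth <- toy_truth(n = 8, n_pre = 2, h = 800)
  cnt <- simulate_counts_from(truth, seed = 38)
  fit <- backcalc(cnt, truth$leaving, rule = truth$rule)
  expect_equal(fit$loglik, log_likelihood(cnt, fitted(fit)), tolerance = 1e-9)
  expect_equal(unname(coef(fit)[, "h"]), fit$params$h)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  r <- residuals(fit)
  cells <- !is.na(r)
  expect_equal(r[cells], ((unclass(cnt) - unclass(fitted(fit))) /
                            sqrt(unclass(fitted(fit))))[cells])
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "count_matrix")
})
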