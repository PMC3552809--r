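#' @export
print.backcalc <- function(x, ...) {
  g <- x$grid
  cat("Multi-state back-calculation fit\n")
  cat(sprintf("  grid: onset %d-%d, observation window %d-%d\n",
              g$first_onset_year, g$last_year, g$first_obs_year, g$last_year))
  cat(sprintf("  observed registrations: %d\n", sum(x$cohort_observed)))
  cat(sprintf("  log-likelihood: %.4f (%s, %d gradient evaluations)\n",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  cat(sprintf("  estimated incidence: total %.1f, peak %.1f in %d\n",
              sum(x$params$h), max(x$params$h),
              grid_years(g)[which.max(x$params$h)]))
  invisible(x)
}

#' Summarise a back-calculation fit
#'
#' The summary table has one row per grid year with the fitted incidence
#' `h`, registration probability `p` (pre-observation years carry the rule
#' value), the assumed leaving rate `q`, the observed registrations
#' contributed by the onset cohort, and a weak-identifiability flag for
#' cohorts contributing fewer than `weak_min_count` observed registrations
#' or at most two observable cells (notably the final onset years, whose
#' incidence is informed by very few lags).
#'
#' @param object a [backcalc()] fit.
#' @param ... unused.
#' @return A `"summary.backcalc"` object wrapping the per-year table.
#' @export
summary.backcalc <- function(object, ...) {
  g <- object$grid
  tab <- data.frame(
    year = grid_years(g),
    h = object$params$h,
    p = object$params$p,
    q = object$leaving$q,
    observed = as.vector(object$cohort_observed),
    n_cells = as.vector(object$cohort_cells),
    weak = as.vector(object$cohort_observed) < object$settings$weak_min_count |
      as.vector(object$cohort_cells) <= 2L)
  structure(list(table = tab, loglik = object$loglik,
                 converged = object$converged,
                 n_iterations = object$n_iterations,
                 max_abs_gradient = object$max_abs_gradient,
                 settings = object$settings, scenario = object$scenario),
            class = "summary.backcalc")
}

#' @export
print.summary.backcalc <- function(x, digits = 4, ...) {
  cat("Multi-state back-calculation fit\n")
  if (!is.null(x$scenario)) cat(sprintf("  scenario: %s\n", x$scenario))
  cat(sprintf("  log-likelihood %.4f, %s, max |gradient| %.2e\n",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$max_abs_gradient))
  tab <- x$table
  tab$h <- round(tab$h, 1)
  tab$p <- signif(tab$p, digits)
  tab$weak <- ifelse(tab$weak, "*", "")
  print(tab, row.names = FALSE)
  if (any(x$table$weak))
    cat("* weakly identified cohort (few observed registrations or lags)\n")
  invisible(x)
}

#' @export
coef.backcalc <- function(object, type = c("matrix", "h", "p"), ...) {
  type <- match.arg(type)
  yrs <- grid_years(object$grid)
  switch(type,
         h = stats::setNames(object$params$h, yrs),
         p = stats::setNames(object$params$p, yrs),
         matrix = {
           m <- cbind(h = object$params$h, p = object$params$p)
           rownames(m) <- yrs
           m
         })
}

#' @export
logLik.backcalc <- function(object, ...) {
  n <- n_years(object$grid)
  npar <- n + if (is.null(object$fixed_p))
    length(obs_years(object$grid)) else 0L
  structure(object$loglik, df = npar,
            nobs = nrow(model_cells(object$grid, observed_only = TRUE)),
            class = "logLik")
}

#' @export
fitted.backcalc <- function(object, ...) object$mu_hat

#' Residuals of a back-calculation fit
#'
#' Pearson residuals `(N - mu) / sqrt(mu)` or signed square-root deviance
#' residuals, on the observable cells; cells outside the observation
#' window are `NA`.
#'
#' @param object a [backcalc()] fit.
#' @param type `"pearson"` or `"deviance"`.
#' @param ... unused.
#' @return A matrix in the [count_matrix()] layout.
#' @export
residuals.backcalc <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  g <- object$grid
  cells <- model_cells(g, observed_only = TRUE)
  idx <- cbind(cells$i, cells$j)
  N <- object$counts[idx]; mu <- object$mu_hat[idx]
  r <- if (type == "pearson") {
    ifelse(mu > 0, (N - mu) / sqrt(mu), 0)
  } else {
    sign(N - mu) * sqrt(cell_deviance(N, mu))
  }
  out <- matrix(NA_real_, n_years(g), n_years(g),
                dimnames = dimnames(object$mu_hat))
  out[idx] <- r
  out
}

#' Parametric simulation from a fitted model
#'
#' Draws new observable count matrices with independent Poisson cells at
#' the fitted expected values (a parametric bootstrap of the observed
#' table).  For career-level simulation from explicit parameters use
#' [simulate_careers()].
#'
#' @param object a [backcalc()] fit.
#' @param nsim number of datasets.
#' @param seed optional seed, restored-on-exit semantics as in
#'   [stats::simulate()].
#' @param ... unused.
#' @return A list of `nsim` [count_matrix()] objects.
#' @export
simulate.backcalc <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  g <- object$grid
  cells <- model_cells(g, observed_only = TRUE)
  idx <- cbind(cells$i, cells$j)
  mu <- object$mu_hat[idx]
  n <- n_years(g)
  lapply(seq_len(nsim), function(s) {
    m <- matrix(0, n, n)
    m[idx] <- stats::rpois(length(mu), mu)
    count_matrix(g, m)
  })
}

#' Plot a back-calculation fit
#'
#' Two panels: estimated yearly incidence `h_t` (with the observation
#' window shaded conceptually by a vertical line at its first year) and
#' the registration probability `p_t`, with the pre-observation rule
#' segment drawn dashed.
#'
#' @param x a [backcalc()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.backcalc <- function(x, ...) {
  g <- x$grid
  yrs <- grid_years(g)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(yrs, x$params$h, type = "l", xlab = "year",
                 ylab = "new users / year", main = "Estimated incidence h_t", ...)
  graphics::abline(v = g$first_obs_year, lty = 3, col = "grey40")
  pre <- yrs < g$first_obs_year
  graphics::plot(yrs, x$params$p, type = "n", xlab = "year",
                 ylab = "P(first registration)", main = "Registration probability p_t")
  if (any(pre))
    graphics::lines(yrs[pre], x$params$p[pre], lty = 2)
  graphics::lines(yrs[!pre], x$params$p[!pre])
  graphics::abline(v = g$first_obs_year, lty = 3, col = "grey40")
  invisible(x)
}
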