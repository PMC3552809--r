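#' Gamma shape and scale from a mean and standard deviation
#'
#' Moment matching: `shape = mean^2 / sd^2`, `scale = sd^2 / mean`, so the
#' gamma distribution has exactly the requested mean and standard
#' deviation.  Used to perturb assumed rates in the bootstrap.
#'
#' @param mean positive mean.
#' @param sd positive standard deviation.
#' @return A list with components `shape` and `scale`.
#' @examples
#' gamma_from_mean_sd(0.01, 0.01)  # shape 1, scale 0.01: exponential
#' gamma_from_mean_sd(0.04, 0.01)  # shape 16, scale 0.0025
#' @export
gamma_from_mean_sd <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L,
            length(sd) == 1L)
  if (!(mean > 0) || !(sd > 0))
    stop("mean and sd must be positive", call. = FALSE)
  list(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Two-part bootstrap for a back-calculation fit
#'
#' Each resample (i) redraws the observed registration records with
#' replacement, and (ii) perturbs the assumed quantities — the flat
#' pre-observation registration level and the yearly cessation rate — by
#' gamma draws whose mean is the assumed value and whose standard
#' deviation is `assumption_sd`, then rebuilds the leaving schedule and
#' refits the model.  Percentile confidence bands are taken across the
#' converged replicates.
#'
#' When individual `records` are available they are case-resampled; with
#' aggregate-only input the observed cells are resampled multinomially
#' (holding the total fixed), which for a table whose records carry no
#' further fields induces the same resampling distribution.
#'
#' @param object a [backcalc()] fit.
#' @param records optional data frame of the observed individual records
#'   (columns `onset_year`, `treatment_year`), e.g. from
#'   [observed_records()].
#' @param n_resamples number of bootstrap replicates (500 in the flagship
#'   analysis).
#' @param assumption_sd standard deviation of the gamma perturbations
#'   (default 0.01); `0` disables perturbation entirely.
#' @param perturb which assumed quantities to perturb.
#' @param pre_obs_mode `"level"` draws one perturbed flat level and lets
#'   the ramp re-link to each replicate's estimated first-window `p`
#'   (the ramp years are defined by interpolation, not independent
#'   guesses); `"independent"` draws each pre-observation year around its
#'   point-estimate rule value and freezes them for the replicate.
#' @param level confidence level for the percentile bands.
#' @param seed integer seed making the replicate set reproducible.
#' @return An object of class `"bc_boot"`: replicate matrices `h` and `p`
#'   (one row per converged replicate), `ci_h` and `ci_p` (rows `lower`,
#'   `upper`), per-replicate resampled totals, the failure count
#'   `n_failed`, and the point fit.
#' @export
bc_bootstrap <- function(object, records = NULL, n_resamples = 500,
                         assumption_sd = 0.01,
                         perturb = c("pre_obs_p", "cessation"),
                         pre_obs_mode = c("level", "independent"),
                         level = 0.95, seed = NULL) {
  stopifnot(inherits(object, "backcalc"), n_resamples >= 1,
            assumption_sd >= 0, level > 0, level < 1)
  pre_obs_mode <- match.arg(pre_obs_mode)
  perturb <- match.arg(perturb, c("pre_obs_p", "cessation"), several.ok = TRUE)
  grid <- object$grid
  n <- n_years(grid)
  if (!is.null(seed)) set.seed(seed)

  if (!is.null(records)) {
    records <- observed_records(records, grid)
    if (nrow(records) != sum(observed_cells_sum(object$counts)))
      warning("record table size differs from the fitted count total",
              call. = FALSE)
  }
  cells <- model_cells(grid, observed_only = TRUE)
  idx <- cbind(cells$i, cells$j)
  N0 <- object$counts[idx]
  total <- sum(N0)

  cess0 <- object$leaving$cessation
  cess_mean <- mean(cess0)
  flat0 <- object$rule$flat_value
  rr <- resolve_rule(object$rule, grid)
  n_pre <- grid$first_obs_year - grid$first_onset_year
  gam_flat <- if (assumption_sd > 0) gamma_from_mean_sd(flat0, assumption_sd)
  gam_cess <- if (assumption_sd > 0) gamma_from_mean_sd(cess_mean, assumption_sd)

  h_mat <- matrix(NA_real_, n_resamples, n)
  p_mat <- matrix(NA_real_, n_resamples, n)
  ll <- rep(NA_real_, n_resamples)
  tot_b <- rep(NA_real_, n_resamples)
  ok <- logical(n_resamples)

  # part 1 for every replicate first (case resampling), then part 2 (gamma
  # perturbation of the assumptions): with the two phases on separate
  # stretches of the RNG stream, runs at matched seeds share identical
  # resamples whatever the perturbation settings, so disabling the
  # perturbation is directly comparable replicate by replicate
  counts_list <- vector("list", n_resamples)
  for (b in seq_len(n_resamples)) {
    if (!is.null(records)) {
      take <- sample.int(nrow(records), nrow(records), replace = TRUE)
      counts_list[[b]] <- aggregate_records(records[take, , drop = FALSE], grid)
    } else {
      m <- matrix(0, n, n)
      m[idx] <- stats::rmultinom(1L, total, N0 / total)[, 1L]
      counts_list[[b]] <- count_matrix(grid, m)
    }
    tot_b[b] <- sum(observed_cells_sum(counts_list[[b]]))
  }

  for (b in seq_len(n_resamples)) {
    counts_b <- counts_list[[b]]
    # part 2: gamma perturbation of the assumed quantities
    flat_b <- flat0
    cess_b <- cess0
    if (assumption_sd > 0 && "pre_obs_p" %in% perturb && n_pre > 0L)
      flat_b <- stats::rgamma(1L, shape = gam_flat$shape, scale = gam_flat$scale)
    if (assumption_sd > 0 && "cessation" %in% perturb)
      cess_b <- cess0 + (stats::rgamma(1L, shape = gam_cess$shape,
                                       scale = gam_cess$scale) - cess_mean)
    fit_b <- tryCatch({
      leaving_b <- leaving_schedule(grid, object$leaving$mortality, cess_b)
      if (pre_obs_mode == "level" || n_pre == 0L) {
        rule_b <- pre_obs_rule(flat_value = min(max(flat_b, 1e-6), 0.999),
                               flat_until = rr$flat_until)
        backcalc(counts_b, leaving_b, rule = rule_b,
                 fixed_p = object$fixed_p,
                 link = if (identical(object$link, "two_stage")) "two_stage" else "simultaneous",
                 identify = object$identify, control = object$settings)
      } else {
        # independent per-year draws around the point-estimate rule values,
        # frozen for this replicate via the two-stage path with zero ramp
        p_pre_hat <- object$params$p[seq_len(n_pre)]
        p_pre_b <- vapply(p_pre_hat, function(m) {
          if (assumption_sd > 0 && "pre_obs_p" %in% perturb) {
            g <- gamma_from_mean_sd(m, assumption_sd)
            stats::rgamma(1L, shape = g$shape, scale = g$scale)
          } else m
        }, 0)
        backcalc_frozen_pre(counts_b, leaving_b, p_pre_b, object)
      }
    }, error = function(e) NULL)
    if (!is.null(fit_b) && fit_b$converged) {
      ok[b] <- TRUE
      h_mat[b, ] <- fit_b$params$h
      p_mat[b, ] <- fit_b$params$p
      ll[b] <- fit_b$loglik
    }
  }

  if (sum(ok) < 2L)
    stop("fewer than 2 converged bootstrap replicates", call. = FALSE)
  yrs <- grid_years(grid)
  colnames(h_mat) <- colnames(p_mat) <- yrs
  structure(list(
    h = h_mat[ok, , drop = FALSE], p = p_mat[ok, , drop = FALSE],
    loglik = ll[ok], resample_totals = tot_b, n_failed = sum(!ok), level = level,
    ci_h = bc_percentile_band(h_mat[ok, , drop = FALSE], level),
    ci_p = bc_percentile_band(p_mat[ok, , drop = FALSE], level),
    point = object, settings = list(n_resamples = n_resamples,
                                    assumption_sd = assumption_sd,
                                    perturb = perturb,
                                    pre_obs_mode = pre_obs_mode, seed = seed)),
    class = "bc_boot")
}

# refit with every pre-observation p frozen at given values (used by the
# independent per-year perturbation mode)
backcalc_frozen_pre <- function(counts, leaving, p_pre, point) {
  fit <- backcalc_engine(counts, leaving, rule = point$rule, start = NULL,
                         fixed_p = point$fixed_p, control = point$settings,
                         frozen_pre = pmin(pmax(p_pre, 1e-8), 0.999))
  if (identical(point$identify, "smooth")) fit <- ridge_select(fit) else
    fit$identify <- "none"
  fit
}

#' Percentile band across bootstrap replicates
#'
#' Columnwise empirical quantiles at `(1 - level) / 2` and
#' `1 - (1 - level) / 2`.
#'
#' @param replicates matrix with one row per replicate.
#' @param level confidence level.
#' @return A 2-row matrix with rows `lower` and `upper`.
#' @export
bc_percentile_band <- function(replicates, level = 0.95) {
  stopifnot(is.matrix(replicates), nrow(replicates) >= 2, level > 0, level < 1)
  a <- (1 - level) / 2
  band <- apply(replicates, 2L, stats::quantile, probs = c(a, 1 - a),
                names = FALSE, type = 7)
  rownames(band) <- c("lower", "upper")
  band
}

#' @export
print.bc_boot <- function(x, ...) {
  cat(sprintf("Bootstrap: %d converged replicates (%d failed), %.0f%% percentile bands\n",
              nrow(x$h), x$n_failed, 100 * x$level))
  cat(sprintf("  assumption sd %.3g, perturbed: %s, pre-obs mode %s\n",
              x$settings$assumption_sd,
              paste(x$settings$perturb, collapse = "+"),
              x$settings$pre_obs_mode))
  invisible(x)
}

#' Summarise a bootstrap as a per-year table
#'
#' @param object a `"bc_boot"` object.
#' @param pop optional population denominators (one per grid year) adding
#'   rate columns per 1,000 via [to_rates()]; replicates are converted to
#'   rates before taking percentiles (order-preserving for fixed
#'   denominators).
#' @param ... unused.
#' @return A data frame with columns `year`, `h_hat`, `h_lo`, `h_hi`,
#'   `p_hat`, `p_lo`, `p_hi` and, with `pop`, `rate`, `rate_lo`, `rate_hi`.
#' @export
summary.bc_boot <- function(object, pop = NULL, ...) {
  fitpt <- object$point
  yrs <- grid_years(fitpt$grid)
  out <- data.frame(year = yrs,
                    h_hat = fitpt$params$h,
                    h_lo = object$ci_h["lower", ], h_hi = object$ci_h["upper", ],
                    p_hat = fitpt$params$p,
                    p_lo = object$ci_p["lower", ], p_hi = object$ci_p["upper", ])
  if (!is.null(pop)) {
    rates <- sweep(object$h, 2L, pop, "/") * 1000
    band <- bc_percentile_band(rates, object$level)
    out$rate <- to_rates(fitpt$params$h, pop)
    out$rate_lo <- band["lower", ]; out$rate_hi <- band["upper", ]
  }
  out
}

#' @export
confint.bc_boot <- function(object, parm = c("h", "p"), level = NULL, ...) {
  parm <- match.arg(parm)
  if (is.null(level)) level <- object$level
  t(bc_percentile_band(object[[parm]], level))
}

#' @export
plot.bc_boot <- function(x, ...) {
  s <- summary(x)
  graphics::plot(s$year, s$h_hat, type = "l", ylim = range(s$h_lo, s$h_hi),
                 xlab = "year", ylab = "new users / year",
                 main = sprintf("Incidence with %.0f%% bootstrap band", 100 * x$level),
                 ...)
  graphics::lines(s$year, s$h_lo, lty = 2)
  graphics::lines(s$year, s$h_hi, lty = 2)
  invisible(x)
}
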