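#' Load individual registration records from delimited text
#'
#' Reads (or accepts) a table with columns `onset_year`, `treatment_year`,
#' optional `stratum` and optional age columns `onset_age`,
#' `treatment_age`.  Rows are filtered to the grid (onset year inside the
#' grid, registration year inside the observation window) and to the
#' optional age ranges; dropped rows are tallied per reason.  Rows with a
#' registration year before the onset year violate causality and abort the
#' load with their row numbers.  Rows with a missing stratum stay in the
#' pooled matrix but are excluded from the per-stratum matrices.
#'
#' @param x file path to a tab-delimited file with a header, or a data
#'   frame.
#' @param grid a [year_grid()].
#' @param onset_age_range optional `c(min, max)` filter on `onset_age`
#'   (e.g. `c(10, 44)`).
#' @param treatment_age_range optional `c(min, max)` filter on
#'   `treatment_age` (e.g. `c(15, 54)`).
#' @return An object of class `"bc_records"`: list with `records` (kept
#'   rows), `pooled` ([count_matrix()]), `strata` (named list of count
#'   matrices, possibly empty), and `dropped` (data frame of reason,
#'   count).
#' @export
load_records <- function(x, grid, onset_age_range = NULL,
                         treatment_age_range = NULL) {
  stopifnot(inherits(grid, "year_grid"))
  df <- if (is.character(x)) utils::read.delim(x, na.strings = c("NA", "")) else x
  if (!all(c("onset_year", "treatment_year") %in% names(df)))
    stop("records need columns onset_year and treatment_year", call. = FALSE)
  df$onset_year <- suppressWarnings(as.numeric(df$onset_year))
  df$treatment_year <- suppressWarnings(as.numeric(df$treatment_year))

  dropped <- list()
  note <- function(reason, keep) {
    n_drop <- sum(!keep)
    if (n_drop > 0) dropped[[reason]] <<- n_drop
    keep
  }
  bad_year <- is.na(df$onset_year) | is.na(df$treatment_year) |
    df$onset_year != round(df$onset_year) |
    df$treatment_year != round(df$treatment_year)
  df <- df[note("malformed_year", !bad_year), , drop = FALSE]

  causal <- df$treatment_year >= df$onset_year
  if (any(!causal))
    stop(sprintf("registration before onset in row(s): %s",
                 paste(utils::head(which(!causal), 20L), collapse = ", ")),
         call. = FALSE)

  df <- df[note("onset_outside_grid",
                df$onset_year >= grid$first_onset_year &
                  df$onset_year <= grid$last_year), , drop = FALSE]
  df <- df[note("treatment_outside_window",
                df$treatment_year >= grid$first_obs_year &
                  df$treatment_year <= grid$last_year), , drop = FALSE]
  if (!is.null(onset_age_range) && "onset_age" %in% names(df))
    df <- df[note("onset_age",
                  !is.na(df$onset_age) & df$onset_age >= onset_age_range[1] &
                    df$onset_age <= onset_age_range[2]), , drop = FALSE]
  if (!is.null(treatment_age_range) && "treatment_age" %in% names(df))
    df <- df[note("treatment_age",
                  !is.na(df$treatment_age) &
                    df$treatment_age >= treatment_age_range[1] &
                    df$treatment_age <= treatment_age_range[2]), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "grid") <- grid

  strata <- list()
  if ("stratum" %in% names(df)) {
    has <- !is.na(df$stratum) & nzchar(as.character(df$stratum))
    if (sum(!has) > 0) dropped[["missing_stratum_excluded_from_strata"]] <- sum(!has)
    for (s in sort(unique(as.character(df$stratum[has]))))
      strata[[s]] <- aggregate_records(df[has & df$stratum == s, , drop = FALSE], grid)
  }
  structure(list(
    records = df,
    pooled = aggregate_records(df, grid),
    strata = strata,
    dropped = data.frame(reason = names(dropped),
                         n = as.integer(unlist(dropped, use.names = FALSE)))),
    class = "bc_records")
}

#' @export
print.bc_records <- function(x, ...) {
  cat(sprintf("Loaded %d observed records", nrow(x$records)))
  if (length(x$strata))
    cat(sprintf(" in %d strata (%s)", length(x$strata),
                paste(names(x$strata), collapse = ", ")))
  cat("\n")
  if (nrow(x$dropped)) {
    cat("Dropped rows:\n")
    for (k in seq_len(nrow(x$dropped)))
      cat(sprintf("  %s: %d\n", x$dropped$reason[k], x$dropped$n[k]))
  }
  invisible(x)
}

#' Convert yearly counts to rates per 1,000 population
#'
#' @param h yearly counts (e.g. estimated incidence).
#' @param pop yearly population denominators, same length.
#' @param per reporting base (default 1,000).
#' @return `per * h / pop`.
#' @export
to_rates <- function(h, pop, per = 1000) {
  if (length(pop) != length(h))
    stop("population denominators missing for some years", call. = FALSE)
  if (any(is.na(pop)) || any(pop <= 0))
    stop("population denominators must be positive", call. = FALSE)
  per * h / pop
}

#' Goodness of fit by onset cohort: observed versus expected curves
#'
#' For every onset year the observed counts `N_ij` and fitted expected
#' counts `mu_ij` over the observable registration years, plus the
#' per-cohort Poisson deviance.  Cohorts with zero observed and zero
#' expected counts everywhere are flagged and excluded from plotting.
#'
#' @param counts a [count_matrix()].
#' @param mu an `"expected_matrix"` on the same grid (e.g.
#'   `fitted(fit)`).
#' @return An object of class `"bc_gof"`: `curves` (long data frame with
#'   `onset_year`, `treatment_year`, `observed`, `expected`), `deviance`
#'   (per-cohort data frame with `deviance`, `n_cells`, `observed`,
#'   `empty`), and `mean_cell_deviance` over all observable cells.
#' @export
gof_cohort_curves <- function(counts, mu) {
  stopifnot(inherits(counts, "count_matrix"), inherits(mu, "expected_matrix"))
  g <- attr(counts, "grid")
  check_same_grid(g, attr(mu, "grid"))
  yrs <- grid_years(g)
  cells <- model_cells(g, observed_only = TRUE)
  idx <- cbind(cells$i, cells$j)
  N <- counts[idx]; m <- mu[idx]
  curves <- data.frame(onset_year = yrs[cells$i], treatment_year = yrs[cells$j],
                       observed = N, expected = m)
  dev <- cell_deviance(N, m)
  per <- rowsum(cbind(dev = dev, observed = N, expected = m, one = 1), cells$i)
  cohort <- data.frame(onset_year = yrs[as.integer(rownames(per))],
                       deviance = per[, "dev"],
                       n_cells = as.integer(per[, "one"]),
                       observed = per[, "observed"],
                       empty = per[, "observed"] == 0 & per[, "expected"] == 0)
  rownames(cohort) <- NULL
  structure(list(curves = curves, deviance = cohort,
                 mean_cell_deviance = sum(dev) / length(dev), grid = g),
            class = "bc_gof")
}

#' @export
print.bc_gof <- function(x, ...) {
  cat(sprintf("Goodness of fit: %d cohorts, mean per-cell scaled deviance %.3f\n",
              sum(!x$deviance$empty), x$mean_cell_deviance))
  invisible(x)
}

#' @export
plot.bc_gof <- function(x, cohorts = NULL, ...) {
  cv <- x$curves
  keep_cohorts <- x$deviance$onset_year[!x$deviance$empty]
  if (is.null(cohorts)) cohorts <- utils::head(keep_cohorts, 12L)
  cohorts <- intersect(cohorts, keep_cohorts)
  nc <- length(cohorts)
  if (nc == 0) stop("no non-empty cohorts to plot", call. = FALSE)
  dims <- c(ceiling(nc / ceiling(sqrt(nc))), ceiling(sqrt(nc)))
  op <- graphics::par(mfrow = dims, mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  for (co in cohorts) {
    d <- cv[cv$onset_year == co, ]
    graphics::plot(d$treatment_year, d$observed, type = "p", pch = 16, cex = 0.6,
                   xlab = "", ylab = "", main = co,
                   ylim = range(0, d$observed, d$expected))
    graphics::lines(d$treatment_year, d$expected)
  }
  invisible(x)
}

#' Lag-time distributions by onset cohort
#'
#' For each onset cohort the normalised distribution of the lag
#' `d = j - i` (whole years from onset to first registration), conditional
#' on registration inside the observation window and strictly before
#' `cutoff_year`.  Computed identically from observed counts or expected
#' counts so the two can be overlaid.  The default cutoff excludes the
#' final grid year (registration strictly before it).
#'
#' @param x a [count_matrix()] or `"expected_matrix"`.
#' @param cutoff_year registrations must satisfy `j < cutoff_year`
#'   (default: the grid's last year).
#' @return A data frame with columns `onset_year`, `lag`, `mass` (masses
#'   sum to 1 within each cohort that has any eligible mass); cohorts with
#'   no eligible cells are reported in the `"empty_cohorts"` attribute.
#' @export
lag_distributions <- function(x, cutoff_year = NULL) {
  stopifnot(inherits(x, "count_matrix") || inherits(x, "expected_matrix"))
  g <- attr(x, "grid")
  if (is.null(cutoff_year)) cutoff_year <- g$last_year
  if (cutoff_year <= g$first_obs_year || cutoff_year > g$last_year + 1L)
    stop("cutoff_year must lie inside the observation window", call. = FALSE)
  yrs <- grid_years(g)
  cells <- model_cells(g, observed_only = TRUE)
  keep <- yrs[cells$j] < cutoff_year
  cells <- cells[keep, , drop = FALSE]
  v <- x[cbind(cells$i, cells$j)]
  out <- data.frame(onset_year = yrs[cells$i], lag = cells$j - cells$i, mass = v)
  empty <- integer(0)
  res <- lapply(split(out, out$onset_year), function(d) {
    tot <- sum(d$mass)
    if (tot > 0) d$mass <- d$mass / tot else d$mass <- NA_real_
    d
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  cohorts_all <- yrs
  eligible <- unique(out$onset_year[!is.na(out$mass)])
  no_cells <- setdiff(cohorts_all, unique(out$onset_year))
  zero_mass <- setdiff(unique(out$onset_year), eligible)
  attr(out, "empty_cohorts") <- sort(c(no_cells, zero_mass))
  out
}

#' Refit the model under several leaving-rate scenarios
#'
#' Fits one model per scenario (rebuilding `q_t` from the base mortality
#' curve plus the scenario's offset and cessation rate) and returns a long
#' table suitable for overlaying the sensitivity of the incidence curve to
#' the exit-rate assumptions.  Per-scenario failures are logged and the
#' remaining scenarios proceed.
#'
#' @param counts a [count_matrix()].
#' @param mortality base yearly mortality rates (one per grid year), e.g.
#'   [mortality_curve()].
#' @param scenarios list of [scenario()] objects (default
#'   [sensitivity_scenarios()]).
#' @param rule a [pre_obs_rule()].
#' @param pop optional population denominators adding a `rate` column.
#' @param control a [bc_control()].
#' @return An object of class `"bc_sensitivity"`: `fits` (named list of
#'   [backcalc()] fits), `table` (long data frame with `scenario`, `year`,
#'   `h_hat`, `p_hat` and optionally `rate`), `failed` (named character
#'   vector of error messages).
#' @export
run_sensitivity <- function(counts, mortality, scenarios = sensitivity_scenarios(),
                            rule = pre_obs_rule(), pop = NULL,
                            control = bc_control()) {
  stopifnot(inherits(counts, "count_matrix"))
  grid <- attr(counts, "grid")
  fits <- list(); failed <- character(0); rows <- list()
  for (sc in scenarios) {
    res <- tryCatch({
      lv <- leaving_schedule(grid, mortality, scenario = sc)
      backcalc(counts, lv, rule = rule, control = control)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[sc$name] <- conditionMessage(res)
      next
    }
    fits[[sc$name]] <- res
    row <- data.frame(scenario = sc$name, year = grid_years(grid),
                      h_hat = res$params$h, p_hat = res$params$p)
    if (!is.null(pop)) row$rate <- to_rates(res$params$h, pop)
    rows[[sc$name]] <- row
  }
  if (!length(fits)) stop("every scenario failed to fit", call. = FALSE)
  structure(list(fits = fits, table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 failed = failed), class = "bc_sensitivity")
}

#' @export
print.bc_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: %d scenario fits", length(x$fits)))
  if (length(x$failed)) cat(sprintf(" (%d failed)", length(x$failed)))
  cat("\n")
  tot <- vapply(x$fits, function(f) sum(f$params$h), 0)
  for (nm in names(tot))
    cat(sprintf("  %s: total incidence %.1f\n", nm, tot[nm]))
  invisible(x)
}

#' @export
plot.bc_sensitivity <- function(x, ...) {
  tab <- x$table
  scs <- unique(tab$scenario)
  graphics::plot(range(tab$year), range(tab$h_hat), type = "n",
                 xlab = "year", ylab = "new users / year",
                 main = "Incidence under leaving-rate scenarios")
  for (k in seq_along(scs))
    graphics::lines(tab$year[tab$scenario == scs[k]],
                    tab$h_hat[tab$scenario == scs[k]], col = k, lty = k)
  graphics::legend("topright", legend = scs, col = seq_along(scs),
                   lty = seq_along(scs), cex = 0.7, bty = "n")
  invisible(x)
}
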