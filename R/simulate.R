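#' Specification of a stochastic career simulation
#'
#' Describes a cohort simulation through the three states: yearly Poisson
#' onsets at rate `h_i`, then for every active, not-yet-registered user a
#' yearly competing choice between first registration (probability `p_k`),
#' exit by death or cessation (`q_k`) and staying active
#' (`1 - p_k - q_k`), truncated at the grid's last year.
#'
#' Two conventions are offered for the onset year, where exposure averages
#' about half a year.  The `"matched"` convention (default) draws treated
#' with probability `0.5 * p_i`, staying with probability `1 - p_i - q_i`,
#' and exiting with the residual `q_i + 0.5 * p_i`; this reproduces the
#' expected-count formula of [expected_counts()] exactly in every cell,
#' including `j > i`.  The `"naive"` alternative (treated `0.5 * p_i`,
#' exited `q_i`, stayed `1 - 0.5 * p_i - q_i`) looks natural but is
#' inconsistent with the model's survival product for later cells, and is
#' provided for comparison only.
#'
#' @param grid a [year_grid()].
#' @param params a [parameter_vector()] of true `h` and `p`.
#' @param leaving a [leaving_schedule()] of true exit rates.
#' @param convention onset-year handling, `"matched"` or `"naive"`.
#' @param strata optional named list of `list(params =, leaving =)` pairs
#'   for route-of-administration-style mixtures; when given, `params` and
#'   `leaving` are ignored and each stratum is simulated independently.
#' @param round_onset_prob probability that a record's reported onset year
#'   is corrupted by rounding to the nearest year ending in 0 or 5
#'   (emulating digit preference in self-reported onset); 0 by default and
#'   never corrected for by the estimator.
#' @param seed optional integer seed; identical seeds give identical tables.
#' @return An object of class `"sim_spec"`.
#' @export
sim_spec <- function(grid, params = NULL, leaving = NULL,
                     convention = c("matched", "naive"), strata = NULL,
                     round_onset_prob = 0, seed = NULL) {
  stopifnot(inherits(grid, "year_grid"))
  convention <- match.arg(convention)
  check_part <- function(params, leaving, label) {
    stopifnot(inherits(params, "parameter_vector"),
              inherits(leaving, "leaving_schedule"))
    check_same_grid(grid, params$grid); check_same_grid(grid, leaving$grid)
    mass <- params$p + leaving$q
    if (convention == "naive") mass <- 0.5 * params$p + leaving$q
    if (any(mass > 1))
      stop(sprintf("invalid probability mass (p + q > 1) in stratum %s", label),
           call. = FALSE)
  }
  if (is.null(strata)) {
    check_part(params, leaving, "<pooled>")
  } else {
    if (is.null(names(strata)) || any(!nzchar(names(strata))))
      stop("strata must be a named list", call. = FALSE)
    for (nm in names(strata)) check_part(strata[[nm]]$params, strata[[nm]]$leaving, nm)
  }
  stopifnot(round_onset_prob >= 0, round_onset_prob <= 1)
  structure(list(grid = grid, params = params, leaving = leaving,
                 convention = convention, strata = strata,
                 round_onset_prob = round_onset_prob,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "sim_spec")
}

#' Simulate individual careers through the multi-state model
#'
#' Generates one record per simulated individual with the onset year, the
#' first-registration year (`NA` if never registered within the study
#' period), the exit year and cause (`NA` if never exited), and the
#' stratum label.  Careers still active at the last grid year have both
#' event years `NA`.  Use [observed_records()] for the right-truncated
#' projection actually visible to a register and [aggregate_records()] to
#' build the observed count matrix.
#'
#' @param spec a [sim_spec()].
#' @return A data frame with columns `onset_year`, `treatment_year`,
#'   `exit_year`, `exit_cause`, `stratum`, with the grid attached as
#'   attribute `"grid"`.
#' @examples
#' g <- year_grid(2000, 2003, 2009)
#' lv <- leaving_schedule(g, mortality = 0.02, cessation = 0.04)
#' truth <- parameter_vector(g, h = 100, p = 0.15)
#' rec <- simulate_careers(sim_spec(g, truth, lv, seed = 42))
#' head(rec)
#' @export
simulate_careers <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(spec$seed)
  }
  parts <- if (is.null(spec$strata)) {
    list("1" = list(params = spec$params, leaving = spec$leaving))
  } else spec$strata
  labels <- if (is.null(spec$strata)) NA_character_ else names(parts)
  out <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    out[[k]] <- simulate_stratum(spec$grid, parts[[k]]$params,
                                 parts[[k]]$leaving, spec$convention,
                                 labels[k])
  }
  rec <- do.call(rbind, out)
  if (spec$round_onset_prob > 0 && nrow(rec) > 0) {
    hit <- stats::runif(nrow(rec)) < spec$round_onset_prob
    rounded <- round(rec$onset_year / 5) * 5
    rounded <- pmax(pmin(rounded, rec$treatment_year, na.rm = FALSE),
                    spec$grid$first_onset_year)
    rounded <- ifelse(is.na(rec$treatment_year), pmax(round(rec$onset_year / 5) * 5,
                                                      spec$grid$first_onset_year),
                      rounded)
    rec$onset_year[hit] <- rounded[hit]
  }
  rownames(rec) <- NULL
  attr(rec, "grid") <- spec$grid
  rec
}

simulate_stratum <- function(grid, params, leaving, convention, label) {
  n <- n_years(grid)
  yrs <- grid_years(grid)
  h <- params$h; p <- params$p; q <- leaving$q
  mort_share <- ifelse(leaving$q > 0, leaving$mortality / leaving$q, NA_real_)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    M <- stats::rpois(1L, h[i])
    if (M == 0L) next
    horizon <- i:n
    nh <- length(horizon)
    ptreat <- numeric(nh); pexit <- numeric(nh)
    if (convention == "matched") {
      ptreat[1] <- 0.5 * p[i]
      pexit[1] <- q[i] + 0.5 * p[i]
      S <- 1 - p[i] - q[i]
    } else {
      ptreat[1] <- 0.5 * p[i]
      pexit[1] <- q[i]
      S <- 1 - 0.5 * p[i] - q[i]
    }
    if (nh > 1L) for (d in 2:nh) {
      k <- horizon[d]
      ptreat[d] <- S * p[k]
      pexit[d] <- S * q[k]
      S <- S * (1 - p[k] - q[k])
    }
    prob <- c(ptreat, pexit, S)
    draw <- stats::rmultinom(1L, M, prob)[, 1L]
    ntreat <- draw[seq_len(nh)]
    nexit <- draw[nh + seq_len(nh)]
    nactive <- draw[2L * nh + 1L]
    treat_year <- rep(yrs[horizon], ntreat)
    exit_year <- rep(yrs[horizon], nexit)
    exit_cause <- rep(NA_character_, length(exit_year))
    if (length(exit_year)) {
      ms <- mort_share[year_index(grid, exit_year)]
      ok <- !is.na(ms)
      exit_cause[ok] <- ifelse(stats::runif(sum(ok)) < ms[ok], "death", "cessation")
    }
    res[[i]] <- data.frame(
      onset_year = yrs[i],
      treatment_year = c(treat_year, rep(NA_integer_, length(exit_year) + nactive)),
      exit_year = c(rep(NA_integer_, length(treat_year)), exit_year,
                    rep(NA_integer_, nactive)),
      exit_cause = c(rep(NA_character_, length(treat_year)), exit_cause,
                     rep(NA_character_, nactive)),
      stratum = label)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(onset_year = integer(0), treatment_year = integer(0),
                      exit_year = integer(0), exit_cause = character(0),
                      stratum = character(0))
  out
}

#' Right-truncated observed projection of a record table
#'
#' Keeps only records whose first registration falls inside the
#' observation window; this is what a register actually sees.
#'
#' @param records a record table from [simulate_careers()] or a data frame
#'   with columns `onset_year`, `treatment_year`.
#' @param grid a [year_grid()]; defaults to the table's attached grid.
#' @return The filtered data frame.
#' @export
observed_records <- function(records, grid = attr(records, "grid")) {
  stopifnot(inherits(grid, "year_grid"))
  keep <- !is.na(records$treatment_year) &
    records$treatment_year >= grid$first_obs_year &
    records$treatment_year <= grid$last_year
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  out
}

#' Aggregate records to an observed count matrix
#'
#' Counts records per (onset year, registration year) cell after applying
#' the observation-window projection; the matrix total equals the number
#' of observed records.
#'
#' @inheritParams observed_records
#' @return A [count_matrix()].
#' @export
aggregate_records <- function(records, grid = attr(records, "grid")) {
  obs <- observed_records(records, grid)
  n <- n_years(grid)
  m <- matrix(0, n, n)
  if (nrow(obs)) {
    i <- year_index(grid, obs$onset_year)
    j <- year_index(grid, obs$treatment_year)
    if (any(j < i)) stop("record with registration before onset", call. = FALSE)
    tab <- table(factor(i, levels = seq_len(n)), factor(j, levels = seq_len(n)))
    m <- matrix(as.integer(tab), n, n)
  }
  count_matrix(grid, m)
}

#' Synthetic epidemic specification resembling a rise-peak-decline wave
#'
#' A ready-made [sim_spec()] emulating the shape of a national heroin
#' epidemic observed through a late-opening treatment register: a 36-year
#' onset grid (1971-2006) with a 16-year observation window (1991-2006),
#' unimodal Gaussian-shaped incidence peaking mid-grid (5000 new
#' users/year at 1986 at `h_scale = 1`), registration probability
#' following the pre-observation flat-plus-ramp rule (flat 0.01 through
#' 1981, ramp to 0.08 at 1991) and rising smoothly — continuing the ramp
#' slope across the window boundary, then accelerating quadratically to
#' 0.30 by 2006 — and the default interpolated mortality plus cessation
#' 0.04.  The smooth crossing at 1991 makes the truth satisfy the
#' estimator's default identification convention (see [backcalc()]),
#' giving a self-consistent validation design.  Every value is synthetic:
#' chosen for shape realism, not estimated from any register.
#'
#' @param h_scale multiplier on the incidence curve.
#' @param seed optional seed stored in the spec.
#' @return A [sim_spec()] with the true parameters accessible via
#'   `$params` and `$leaving`.
#' @export
synthetic_epidemic_spec <- function(h_scale = 1, seed = NULL) {
  grid <- year_grid(1971, 1991, 2006)
  yrs <- grid_years(grid)
  h <- 5000 * h_scale * exp(-0.5 * ((yrs - 1986) / 6)^2)
  p_link <- 0.08
  p <- numeric(length(yrs))
  pre <- yrs < grid$first_obs_year
  p[pre] <- apply_pre_obs_rule(pre_obs_rule(flat_until = 1981), p_link, grid)
  # window: initial slope = ramp slope (0.08 - 0.01)/10, quadratic up to 0.30
  d <- yrs[!pre] - grid$first_obs_year
  s <- (p_link - 0.01) / 10
  dmax <- max(d)
  gam <- (0.30 - p_link - s * dmax) / (dmax * (dmax - 1))
  p[!pre] <- p_link + s * d + gam * d * (d - 1)
  leaving <- leaving_schedule(grid, mortality_curve(grid), cessation = 0.04)
  sim_spec(grid, parameter_vector(grid, h, p), leaving, seed = seed)
}

#' Synthetic population denominators
#'
#' A smooth synthetic yearly population series (persons in the reference
#' age band) for converting incidence counts to rates per 1,000 in
#' examples and tests; a mild rise-and-level shape around ten million.
#' Not census data.
#'
#' @param grid a [year_grid()].
#' @param base population level at the grid midpoint.
#' @return A numeric vector, one denominator per grid year.
#' @export
synthetic_population <- function(grid, base = 1e7) {
  yrs <- grid_years(grid)
  mid <- stats::median(yrs)
  round(base * (1 + 0.1 * tanh((yrs - mid) / 10)))
}

#' Write and read record tables as delimited text
#'
#' Tab-delimited with header `onset_year`, `treatment_year`, `stratum`
#' (registration year empty for unobserved rows).
#'
#' @param records a record table.
#' @param path file path.
#' @export
write_records <- function(records, path) {
  keep <- intersect(c("onset_year", "treatment_year", "stratum"), names(records))
  utils::write.table(records[keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
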