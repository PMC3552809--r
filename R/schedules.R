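#' Mortality anchors and interpolated yearly mortality
#'
#' Yearly mortality of active, not-yet-registered users is specified as a
#' small set of (year, rate) anchor points and linearly interpolated to the
#' grid, with constant extrapolation outside the anchor range.  The default
#' anchor set encodes the cohort-study values available for the Spanish
#' epidemic: a smooth rise from 1.0% (1971) to the 1.4% minimum at
#' 1984/1985, the 6.6% maximum in 1995, 1.5% in 1999 and 1.0% by 2006.
#' Only the minimum and maximum of the 1985-1999 cohort series are
#' published, so the default is explicitly an approximation by linear
#' interpolation between those anchors; any full yearly series can be
#' substituted.
#'
#' @return `default_mortality_anchors()` returns a data frame with columns
#'   `year` and `rate`.
#' @export
default_mortality_anchors <- function() {
  data.frame(year = c(1971L, 1984L, 1985L, 1995L, 1999L, 2006L),
             rate = c(0.010, 0.014, 0.014, 0.066, 0.015, 0.010))
}

#' @rdname default_mortality_anchors
#' @param grid a [year_grid()].
#' @param anchors data frame with strictly increasing `year` and `rate` in
#'   `(0, 1)`.
#' @return `mortality_curve()` returns one mortality rate per grid year.
#' @examples
#' g <- year_grid(1971, 1991, 2006)
#' mortality_curve(g)
#' @export
mortality_curve <- function(grid, anchors = default_mortality_anchors()) {
  stopifnot(inherits(grid, "year_grid"), is.data.frame(anchors))
  if (!all(c("year", "rate") %in% names(anchors)))
    stop("anchors need columns year and rate", call. = FALSE)
  if (is.unsorted(anchors$year, strictly = TRUE))
    stop("anchor years must be strictly increasing", call. = FALSE)
  if (any(anchors$rate <= 0) || any(anchors$rate >= 1))
    stop("anchor rates must lie in (0, 1)", call. = FALSE)
  if (nrow(anchors) == 1L) return(rep(anchors$rate, n_years(grid)))
  stats::approx(anchors$year, anchors$rate, xout = grid_years(grid),
                method = "linear", rule = 2)$y
}

#' Sensitivity scenarios over the leaving-rate assumptions
#'
#' A scenario is a constant yearly cessation rate plus an additive offset
#' applied to every year's mortality.  `sensitivity_scenarios()` returns
#' the four standard combinations — cessation 0.04 or 0.02 crossed with
#' mortality offset 0 or +0.01 — with the unmodified-mortality,
#' cessation-0.04 combination first as the primary analysis.
#'
#' @param name scenario label.
#' @param cessation constant yearly cessation probability.
#' @param mortality_offset additive constant applied to every year's
#'   mortality rate.
#' @return `scenario()` returns a `"bc_scenario"`;
#'   `sensitivity_scenarios()` a named list of four.
#' @export
scenario <- function(name, cessation, mortality_offset = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(cessation), length(cessation) == 1L, cessation >= 0,
            is.numeric(mortality_offset), length(mortality_offset) == 1L,
            mortality_offset >= 0)
  structure(list(name = name, cessation = as.numeric(cessation),
                 mortality_offset = as.numeric(mortality_offset)),
            class = "bc_scenario")
}

#' @rdname scenario
#' @export
sensitivity_scenarios <- function() {
  s <- list(
    scenario("cess0.04_offset0.00", cessation = 0.04, mortality_offset = 0),
    scenario("cess0.02_offset0.00", cessation = 0.02, mortality_offset = 0),
    scenario("cess0.04_offset0.01", cessation = 0.04, mortality_offset = 0.01),
    scenario("cess0.02_offset0.01", cessation = 0.02, mortality_offset = 0.01))
  names(s) <- vapply(s, `[[`, "", "name")
  attr(s, "default") <- s[[1L]]$name
  s
}

#' @export
print.bc_scenario <- function(x, ...) {
  cat(sprintf("Scenario %s: cessation %.3f/yr, mortality offset +%.3f/yr\n",
              x$name, x$cessation, x$mortality_offset))
  invisible(x)
}

#' Yearly leaving-rate schedule
#'
#' The leaving rate `q_t` is the yearly probability that an active user
#' exits (dies or permanently ceases) before ever registering; it is the
#' elementwise sum of the mortality and cessation components and is
#' treated as known by the estimator.
#'
#' @param grid a [year_grid()].
#' @param mortality yearly mortality probabilities (length 1 or one per
#'   grid year), e.g. from [mortality_curve()].
#' @param cessation yearly cessation probabilities (length 1 or one per
#'   grid year).
#' @param scenario optional [scenario()]; when supplied, its cessation rate
#'   replaces `cessation` and its offset is added to `mortality`.
#' @return An object of class `"leaving_schedule"` with components
#'   `mortality`, `cessation` and `q` (their sum), all per grid year.
#' @examples
#' g <- year_grid(1971, 1991, 2006)
#' lv <- leaving_schedule(g, mortality_curve(g), cessation = 0.04)
#' head(as.data.frame(lv))
#' @export
leaving_schedule <- function(grid, mortality, cessation = NULL, scenario = NULL) {
  stopifnot(inherits(grid, "year_grid"))
  mortality <- grid_series(mortality, grid, "mortality")
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "bc_scenario"))
    mortality <- mortality + scenario$mortality_offset
    cessation <- scenario$cessation
  }
  if (is.null(cessation))
    stop("supply a cessation rate or a scenario", call. = FALSE)
  cessation <- grid_series(cessation, grid, "cessation")
  if (any(mortality < 0) || any(cessation < 0))
    stop("mortality and cessation must be non-negative", call. = FALSE)
  q <- mortality + cessation
  if (any(q >= 1)) {
    bad <- grid_years(grid)[q >= 1]
    stop(sprintf("leaving rate q_t >= 1 in year(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(grid = grid, mortality = mortality, cessation = cessation,
                 q = q, scenario = if (!is.null(scenario)) scenario$name),
            class = "leaving_schedule")
}

#' @export
print.leaving_schedule <- function(x, ...) {
  cat(sprintf("Leaving schedule %d-%d: q_t in [%.3f, %.3f]%s\n",
              x$grid$first_onset_year, x$grid$last_year, min(x$q), max(x$q),
              if (is.null(x$scenario)) "" else paste0(" (scenario ", x$scenario, ")")))
  invisible(x)
}

#' @export
as.data.frame.leaving_schedule <- function(x, ...) {
  data.frame(year = grid_years(x$grid), mortality = x$mortality,
             cessation = x$cessation, q = x$q)
}

#' Read and write leaving schedules as delimited text
#'
#' Tab-delimited with header `year`, `mortality`, `cessation`, `q`.
#'
#' @param x a [leaving_schedule()].
#' @param path file path.
#' @param grid the [year_grid()] to check the file against.
#' @export
write_schedule <- function(x, path) {
  stopifnot(inherits(x, "leaving_schedule"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, grid) {
  df <- utils::read.delim(path)
  if (!all(c("year", "mortality", "cessation") %in% names(df)))
    stop("schedule file needs columns year, mortality, cessation", call. = FALSE)
  df <- df[order(df$year), ]
  if (!identical(as.integer(df$year), grid_years(grid)))
    stop("schedule years do not match the grid", call. = FALSE)
  leaving_schedule(grid, df$mortality, df$cessation)
}
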