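#' Calendar-year grid for the multi-state model
#'
#' All model quantities (incidence `h_t`, registration probability `p_t`,
#' leaving rate `q_t`, observed and expected counts) are indexed by
#' consecutive calendar years of one grid.  Onset years run over the whole
#' grid; first registrations are observable only inside the window
#' `[first_obs_year, last_year]` (right truncation: people registering
#' before or after the window are invisible).
#'
#' @param first_onset_year first calendar year in which onset can occur.
#' @param first_obs_year first calendar year of observable registrations;
#'   must satisfy `first_onset_year <= first_obs_year <= last_year`.
#' @param last_year last calendar year of the study period.
#' @return An object of class `"year_grid"`.
#' @examples
#' g <- year_grid(1971, 1991, 2006)
#' grid_years(g)
#' @export
year_grid <- function(first_onset_year, first_obs_year, last_year) {
  for (y in list(first_onset_year, first_obs_year, last_year)) {
    if (length(y) != 1L || !is.numeric(y) || is.na(y) || y != round(y))
      stop("grid years must be single whole calendar years", call. = FALSE)
  }
  if (!(first_onset_year <= first_obs_year && first_obs_year <= last_year))
    stop("need first_onset_year <= first_obs_year <= last_year", call. = FALSE)
  structure(
    list(first_onset_year = as.integer(first_onset_year),
         first_obs_year = as.integer(first_obs_year),
         last_year = as.integer(last_year)),
    class = "year_grid")
}

#' @rdname year_grid
#' @param grid a `"year_grid"` object.
#' @export
grid_years <- function(grid) {
  stopifnot(inherits(grid, "year_grid"))
  seq.int(grid$first_onset_year, grid$last_year)
}

#' @rdname year_grid
#' @export
obs_years <- function(grid) {
  stopifnot(inherits(grid, "year_grid"))
  seq.int(grid$first_obs_year, grid$last_year)
}

#' @rdname year_grid
#' @export
n_years <- function(grid) grid$last_year - grid$first_onset_year + 1L

#' @rdname year_grid
#' @param year calendar year(s) to convert to grid indices.
#' @export
year_index <- function(grid, year) {
  idx <- as.integer(year) - grid$first_onset_year + 1L
  if (any(idx < 1L | idx > n_years(grid)))
    stop("year outside grid", call. = FALSE)
  idx
}

same_grid <- function(a, b) {
  identical(unclass(a)[c("first_onset_year", "first_obs_year", "last_year")],
            unclass(b)[c("first_onset_year", "first_obs_year", "last_year")])
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("objects do not share one year grid", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.year_grid <- function(x, ...) {
  cat(sprintf("Year grid: onset %d-%d, registrations observable %d-%d (%d years)\n",
              x$first_onset_year, x$last_year, x$first_obs_year, x$last_year,
              n_years(x)))
  invisible(x)
}

# yearly vector helper: recycle scalars, validate length against the grid
grid_series <- function(x, grid, what) {
  n <- n_years(grid)
  if (length(x) == 1L) x <- rep(as.numeric(x), n)
  if (length(x) != n)
    stop(sprintf("'%s' must have length 1 or %d (one value per grid year)",
                 what, n), call. = FALSE)
  as.numeric(x)
}
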