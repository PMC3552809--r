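#' Observed count matrix of onset year by first-registration year
#'
#' `N[i, j]` holds the number of individuals with onset in year `i` and
#' first registration in year `j`.  Cells with `j < i` are structurally
#' zero; cells with `j` outside the observation window
#' `[first_obs_year, last_year]` are unobservable and are excluded from
#' every likelihood sum.
#'
#' @param grid a [year_grid()].
#' @param counts square numeric matrix of non-negative integers, one row
#'   per onset year and one column per registration year of the grid, or a
#'   long-format data frame with columns `onset_year`, `treatment_year`,
#'   `count`.
#' @return An object of class `"count_matrix"`: the matrix with the grid
#'   attached as attribute `"grid"`.
#' @seealso [read_counts()], [aggregate_records()]
#' @export
count_matrix <- function(grid, counts) {
  stopifnot(inherits(grid, "year_grid"))
  n <- n_years(grid)
  yrs <- grid_years(grid)
  if (is.data.frame(counts)) {
    req <- c("onset_year", "treatment_year", "count")
    if (!all(req %in% names(counts)))
      stop("long-format counts need columns onset_year, treatment_year, count",
           call. = FALSE)
    m <- matrix(0, n, n)
    i <- year_index(grid, counts$onset_year)
    j <- year_index(grid, counts$treatment_year)
    # accumulate duplicates: indexed assignment alone would drop them
    agg <- rowsum(as.numeric(counts$count), (j - 1L) * n + i)
    flat <- as.integer(rownames(agg))
    m[flat] <- agg[, 1L]
    counts <- m
  }
  if (!is.matrix(counts) || nrow(counts) != n || ncol(counts) != n)
    stop(sprintf("counts must be a %d x %d matrix on the grid years", n, n),
         call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  low <- lower.tri(counts)
  if (any(counts[low] != 0))
    stop("cells with treatment year before onset year must be zero",
         call. = FALSE)
  counts[low] <- 0
  dimnames(counts) <- list(onset = yrs, treatment = yrs)
  structure(counts, grid = grid, class = c("count_matrix", "matrix"))
}

#' @export
print.count_matrix <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("Count matrix on %d-%d grid: %d individuals in %d observable cells\n",
              g$first_onset_year, g$last_year,
              sum(observed_cells_sum(x)), nrow(model_cells(g, observed_only = TRUE))))
  invisible(x)
}

# all structurally possible cells i <= j as index pairs on the grid;
# observed_only keeps j inside the observation window
model_cells <- function(grid, observed_only = FALSE) {
  n <- n_years(grid)
  j0 <- if (observed_only) year_index(grid, grid$first_obs_year) else 1L
  j <- rep.int(seq_len(n), times = seq_len(n))      # column index per upper cell
  i <- sequence(seq_len(n))                          # row index i <= j
  keep <- j >= j0
  data.frame(i = i[keep], j = j[keep])
}

observed_cells_sum <- function(counts) {
  g <- attr(counts, "grid")
  cells <- model_cells(g, observed_only = TRUE)
  counts[cbind(cells$i, cells$j)]
}

#' Yearly model parameters: incidence and registration probability
#'
#' Bundles the yearly expected number of new users `h_t` (persons/year,
#' every grid year) and the yearly probability `p_t` of first registration
#' for an active user (every grid year; values before the observation
#' window are normally filled by the pre-observation rule, see
#' [pre_obs_rule()]).
#'
#' @param grid a [year_grid()].
#' @param h non-negative yearly expected counts of new users (length 1 or
#'   one per grid year).
#' @param p yearly registration probabilities in `[0, 1)` (length 1 or one
#'   per grid year).
#' @return An object of class `"parameter_vector"`.
#' @export
parameter_vector <- function(grid, h, p) {
  stopifnot(inherits(grid, "year_grid"))
  h <- grid_series(h, grid, "h")
  p <- grid_series(p, grid, "p")
  if (any(!is.finite(h)) || any(h < 0)) stop("h must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1))
    stop("p must lie in [0, 1)", call. = FALSE)
  structure(list(grid = grid, h = h, p = p), class = "parameter_vector")
}

#' @export
print.parameter_vector <- function(x, ...) {
  cat(sprintf("Yearly parameters %d-%d: total h = %.1f, p in [%.3f, %.3f]\n",
              x$grid$first_onset_year, x$grid$last_year,
              sum(x$h), min(x$p), max(x$p)))
  invisible(x)
}

#' Expected registration counts under the three-state model
#'
#' Computes the expected number of first registrations `mu[i, j]` for onset
#' year `i` and registration year `j`:
#' `mu_ij = h_i * prod_{k=i}^{j-1} (1 - p_k - q_k) * p_j` for `j > i`, the
#' product of expected onsets, the probability of remaining an unregistered
#' active user from `i` through `j - 1`, and the registration probability
#' in `j`.  The same-year cell is half-weighted,
#' `mu_ii = 0.5 * h_i * p_i`, because onset part-way through the year
#' leaves on average about half a year of exposure.
#'
#' @param params a [parameter_vector()].
#' @param leaving a [leaving_schedule()] on the same grid.
#' @return An object of class `"expected_matrix"`: the matrix `mu` with the
#'   grid attached; cells with `j < i` are zero.
#' @examples
#' g <- year_grid(2000, 2000, 2004)
#' pars <- parameter_vector(g, h = 1000, p = 0.1)
#' lv <- leaving_schedule(g, mortality = 0.014, cessation = 0.04)
#' expected_counts(pars, lv)
#' @export
expected_counts <- function(params, leaving) {
  stopifnot(inherits(params, "parameter_vector"),
            inherits(leaving, "leaving_schedule"))
  check_same_grid(params$grid, leaving$grid)
  grid <- params$grid
  n <- n_years(grid)
  h <- params$h; p <- params$p; q <- leaving$q
  r <- 1 - p - q
  if (any(r < 0)) {
    bad <- grid_years(grid)[r < 0]
    stop(sprintf("p_t + q_t exceeds 1 in year(s) %s: survival factor negative",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  mu <- matrix(0, n, n)
  for (i in seq_len(n)) {
    # surv[d + 1] = prod_{k = i}^{i + d - 1} (1 - p_k - q_k), surv[1] = 1
    surv <- cumprod(c(1, r[seq.int(i, length.out = n - i)]))
    mu[i, i:n] <- h[i] * surv * p[i:n]
    mu[i, i] <- 0.5 * h[i] * p[i]
  }
  dimnames(mu) <- list(onset = grid_years(grid), treatment = grid_years(grid))
  structure(mu, grid = grid, class = c("expected_matrix", "matrix"))
}

#' @export
print.expected_matrix <- function(x, ...) {
  g <- attr(x, "grid")
  cells <- model_cells(g, observed_only = TRUE)
  cat(sprintf("Expected counts on %d-%d grid: %.1f expected registrations in window\n",
              g$first_onset_year, g$last_year, sum(x[cbind(cells$i, cells$j)])))
  invisible(x)
}

#' Poisson deconvolution log-likelihood
#'
#' Log-likelihood of the observed counts under independent Poisson cells,
#' `sum over observable cells of (N_ij * log mu_ij - mu_ij)`, dropping the
#' `log(N_ij!)` term, which depends on the data only and therefore shifts
#' the log-likelihood by a constant irrelevant to maximisation and to
#' likelihood comparisons on fixed data.  The sum runs only over cells with
#' registration year inside the observation window; `N = 0, mu = 0` cells
#' contribute exactly 0 (continuous extension of `0 * log 0`).
#'
#' @param counts a [count_matrix()].
#' @param mu an `"expected_matrix"` from [expected_counts()] on the same grid.
#' @return The log-likelihood (a single number, up to the dropped constant).
#' @export
log_likelihood <- function(counts, mu) {
  stopifnot(inherits(counts, "count_matrix"), inherits(mu, "expected_matrix"))
  g <- attr(counts, "grid")
  check_same_grid(g, attr(mu, "grid"))
  cells <- model_cells(g, observed_only = TRUE)
  idx <- cbind(cells$i, cells$j)
  N <- counts[idx]; m <- mu[idx]
  bad <- N > 0 & m == 0
  if (any(bad)) {
    yrs <- grid_years(g)
    k <- which(bad)[1L]
    stop(sprintf(
      "observed count %d in cell (onset %d, treatment %d) has expected value 0: log-likelihood is -Inf",
      N[k], yrs[cells$i[k]], yrs[cells$j[k]]), call. = FALSE)
  }
  pos <- N > 0
  sum(N[pos] * log(m[pos])) - sum(m)
}

# Poisson deviance per observable cell: 2 * (N log(N / mu) - (N - mu)),
# with the N = 0 term reducing to 2 * mu.
cell_deviance <- function(N, mu) {
  d <- 2 * (ifelse(N > 0, N * log(N / mu), 0) - (N - mu))
  d[N == 0 & mu == 0] <- 0
  d
}

#' Read and write count and expected matrices as long-format text
#'
#' Tables are tab-delimited with header `onset_year`, `treatment_year` and
#' a value column (`count` or `mu`); one row per structurally possible cell
#' (onset year not after registration year).  The round trip is lossless.
#'
#' @param x a `"count_matrix"` or `"expected_matrix"`.
#' @param path file path.
#' @param grid the [year_grid()] the file is laid out on (the window is not
#'   stored in the file).
#' @return `read_counts()` returns a `"count_matrix"`; `read_expected()` an
#'   `"expected_matrix"`; the writers return `path` invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  write_cells_long(x, path, "count")
}

#' @rdname write_counts
#' @export
read_counts <- function(path, grid) {
  df <- utils::read.delim(path, check.names = FALSE)
  names(df)[names(df) == "count"] <- "count"
  count_matrix(grid, df[c("onset_year", "treatment_year", "count")])
}

#' @rdname write_counts
#' @export
write_expected <- function(x, path) {
  stopifnot(inherits(x, "expected_matrix"))
  write_cells_long(x, path, "mu")
}

#' @rdname write_counts
#' @export
read_expected <- function(path, grid) {
  df <- utils::read.delim(path, check.names = FALSE)
  n <- n_years(grid)
  m <- matrix(0, n, n)
  m[cbind(year_index(grid, df$onset_year), year_index(grid, df$treatment_year))] <- df$mu
  dimnames(m) <- list(onset = grid_years(grid), treatment = grid_years(grid))
  structure(m, grid = grid, class = c("expected_matrix", "matrix"))
}

write_cells_long <- function(x, path, value_name) {
  g <- attr(x, "grid")
  yrs <- grid_years(g)
  cells <- model_cells(g)
  df <- data.frame(onset_year = yrs[cells$i], treatment_year = yrs[cells$j])
  df[[value_name]] <- x[cbind(cells$i, cells$j)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
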