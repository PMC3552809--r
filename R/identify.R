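#' Slide a fit along its likelihood-invariant ridge
#'
#' The back-calculation likelihood is exactly invariant under a
#' one-parameter family of rescalings (see the Identifiability section of
#' [backcalc()]).  In terms of the window quantities
#' `A_j = prod_{k < j} (1 - p_k - q_k)` (survival from the window start)
#' and `b_j = A_j p_j` (probability that a user active at the window start
#' registers in year `j`), the family scales `b -> b / c` and recovers the
#' transformed probabilities through the forced recursion
#' `A'_{j+1} = A'_j (1 - q_j) - b'_j`, `p'_j = b'_j / A'_j`; incidence
#' absorbs the complementary factor, `h'_i = c h_i A'_i / A_i` for window
#' cohorts and `h'_i = c h_i S_i / S'_i` for earlier cohorts, where `S_i`
#' is the pre-window survival (re-linked through the pre-observation
#' rule unless the fit froze those years).  Every observable expected
#' count, and hence the log-likelihood, is unchanged.
#'
#' @param object a [backcalc()] fit.
#' @param c positive scale factor; `c = 1` is the identity.  Values below
#'   the feasibility limit (where a transformed survival would turn
#'   negative) raise an error.
#' @return A `"backcalc"` object with transformed parameters, refreshed
#'   `mu_hat`, and identical `loglik` (recomputed, asserted equal to
#'   numerical precision).
#' @seealso [backcalc()]
#' @export
ridge_shift <- function(object, c) {
  stopifnot(inherits(object, "backcalc"), is.numeric(c), length(c) == 1L, c > 0)
  par <- ridge_point(object, c)
  if (is.null(par))
    stop("scale factor outside the feasible range of the ridge", call. = FALSE)
  out <- object
  out$params <- parameter_vector(object$grid, par$h, par$p)
  out$mu_hat <- expected_counts(out$params, object$leaving)
  ll <- log_likelihood(object$counts, out$mu_hat)
  if (abs(ll - object$loglik) > 1e-6 * (1 + abs(object$loglik)))
    stop("ridge transform changed the log-likelihood: numerical breakdown")
  out$loglik <- ll
  out$ridge_c <- c * (if (is.null(object$ridge_c)) 1 else object$ridge_c)
  out
}

# transformed (h, p) at scale c, or NULL when infeasible
ridge_point <- function(object, c) {
  grid <- object$grid
  n <- n_years(grid)
  obs0 <- year_index(grid, grid$first_obs_year)
  nw <- n - obs0 + 1L
  p <- object$params$p; h <- object$params$h; q <- object$leaving$q
  pw <- p[obs0:n]; qw <- q[obs0:n]
  A <- c(1, cumprod(1 - pw - qw))[seq_len(nw)]
  b <- A * pw / c
  A2 <- numeric(nw); A2[1L] <- 1
  for (j in seq_len(nw - 1L)) A2[j + 1L] <- A2[j] * (1 - qw[j]) - b[j]
  if (any(A2 <= 0)) return(NULL)
  p2w <- b / A2
  if (any(p2w <= 0) || any(p2w >= 1 - qw)) return(NULL)
  p2 <- p; h2 <- h * c
  p2[obs0:n] <- p2w
  if (obs0 > 1L) {
    pre <- seq_len(obs0 - 1L)
    p2[pre] <- if (is.null(object$p_pre_frozen))
      apply_pre_obs_rule(object$rule, p2w[1L], grid) else object$p_pre_frozen
    if (any(p2[pre] + q[pre] >= 1)) return(NULL)
    s_old <- rev(cumprod(rev(1 - p[pre] - q[pre])))
    s_new <- rev(cumprod(rev(1 - p2[pre] - q[pre])))
    h2[pre] <- h[pre] * c * s_old / s_new
  }
  h2[obs0:n] <- h[obs0:n] * c * A2 / A
  list(h = h2, p = p2)
}

# identification step: among the likelihood-equivalent ridge points, report
# the one whose window registration-probability series is smoothest on the
# log scale, subject to p at the link year staying at or above the
# pre-observation rule's flat level
ridge_select <- function(fit) {
  grid <- fit$grid
  n <- n_years(grid)
  obs0 <- year_index(grid, grid$first_obs_year)
  nw <- n - obs0 + 1L
  if (!is.null(fit$fixed_p) || nw < 3L) {
    fit$identify <- "none"
    return(fit)
  }
  floor_p <- fit$rule$flat_value
  big <- .Machine$double.xmax / 1e6     # finite sentinel keeps optimize() quiet
  rough <- function(lc) {
    par <- ridge_point(fit, exp(lc))
    if (is.null(par)) return(big)
    pw <- par$p[obs0:n]
    if (pw[1L] < floor_p) return(big)
    sum(diff(log(pw), differences = 2L)^2)
  }
  lcs <- seq(log(0.05), log(50), length.out = 301L)
  rv <- vapply(lcs, rough, 0)
  if (all(rv >= big)) {
    fit$identify <- "none"
    warning("ridge selection found no feasible scale; raw optimiser endpoint reported",
            call. = FALSE)
    return(fit)
  }
  i0 <- which.min(rv)
  lo_i <- max(1L, i0 - 1L); hi_i <- min(length(lcs), i0 + 1L)
  if (rv[lo_i] >= big) lo_i <- i0
  if (rv[hi_i] >= big) hi_i <- i0
  lc_star <- lcs[i0]
  if (lo_i < hi_i) {
    opt <- stats::optimize(rough, c(lcs[lo_i], lcs[hi_i]))
    if (opt$objective <= rv[i0]) lc_star <- opt$minimum
  }
  out <- ridge_shift(fit, exp(lc_star))
  out$identify <- "smooth"
  out
}
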