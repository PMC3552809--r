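#' Pre-observation registration probability rule
#'
#' Registration data exist only inside the observation window, so `p_t`
#' cannot be estimated before `first_obs_year`.  Those years are filled
#' deterministically: a flat low level through `flat_until` (no dedicated
#' treatment on offer yet), then a linear ramp from that level up to the
#' value of `p` at `link_year` (the first estimated year).  The linkage is
#' evaluated inside the likelihood at every iteration, so the ramp always
#' ends at the current estimate of `p[link_year]`.
#'
#' Defaults follow the Spanish analysis layout: flat 0.01 through 1981,
#' ramp 1982-1990 up to the 1991 estimate.  `flat_until` and `link_year`
#' left `NULL` are resolved against the fitted grid: `link_year` becomes
#' `first_obs_year` and `flat_until` the midpoint of the pre-observation
#' period (which reproduces 1981 on the 1971/1991 grid).
#'
#' @param flat_value the flat pre-ramp probability (default 0.01).
#' @param flat_until last year of the flat segment (`NULL` = resolve from
#'   the grid).
#' @param link_year year whose estimated `p` anchors the ramp end (`NULL` =
#'   `first_obs_year`).
#' @return An object of class `"pre_obs_rule"`.
#' @export
pre_obs_rule <- function(flat_value = 0.01, flat_until = NULL, link_year = NULL) {
  stopifnot(is.numeric(flat_value), length(flat_value) == 1L,
            flat_value > 0, flat_value < 1)
  structure(list(flat_value = flat_value,
                 flat_until = if (!is.null(flat_until)) as.integer(flat_until),
                 link_year = if (!is.null(link_year)) as.integer(link_year)),
            class = "pre_obs_rule")
}

resolve_rule <- function(rule, grid) {
  stopifnot(inherits(rule, "pre_obs_rule"), inherits(grid, "year_grid"))
  link <- if (is.null(rule$link_year)) grid$first_obs_year else rule$link_year
  if (link != grid$first_obs_year)
    stop("link_year must equal the grid's first_obs_year", call. = FALSE)
  flat_until <- rule$flat_until
  if (is.null(flat_until))
    flat_until <- grid$first_onset_year +
      (grid$first_obs_year - grid$first_onset_year) %/% 2L
  if (flat_until >= link && grid$first_obs_year > grid$first_onset_year)
    stop("flat_until must precede link_year", call. = FALSE)
  list(flat_value = rule$flat_value, flat_until = as.integer(flat_until),
       link_year = as.integer(link))
}

#' @rdname pre_obs_rule
#' @param rule a `"pre_obs_rule"`.
#' @param p_link the registration probability at `link_year`.
#' @param grid a [year_grid()] with `first_obs_year > first_onset_year`.
#' @return `apply_pre_obs_rule()` returns the `p_t` values for the years
#'   `first_onset_year, ..., first_obs_year - 1`, named by year.
#' @examples
#' g <- year_grid(1971, 1991, 2006)
#' apply_pre_obs_rule(pre_obs_rule(flat_until = 1981), p_link = 0.11, g)
#' @export
apply_pre_obs_rule <- function(rule, p_link, grid) {
  stopifnot(is.numeric(p_link), length(p_link) == 1L, p_link > 0, p_link < 1)
  r <- resolve_rule(rule, grid)
  yrs <- seq.int(grid$first_onset_year,
                 length.out = grid$first_obs_year - grid$first_onset_year)
  w <- pre_obs_weights(r, yrs)
  stats::setNames(r$flat_value * (1 - w) + p_link * w, yrs)
}

# ramp weight of p_link per pre-observation year: 0 on the flat segment,
# (t - flat_until) / (link_year - flat_until) on the ramp
pre_obs_weights <- function(resolved, years) {
  w <- (years - resolved$flat_until) / (resolved$link_year - resolved$flat_until)
  pmin(pmax(w, 0), 1)
}

#' Optimiser settings for [backcalc()]
#'
#' The objective is maximised by BFGS with analytic gradients; because the
#' likelihood surface is a long curved valley, the optimiser is restarted
#' (fresh Hessian approximation) until the log-likelihood stops improving.
#'
#' @param reltol relative log-likelihood convergence tolerance within each
#'   BFGS run and across restarts (default `1e-9`).
#' @param maxit maximum iterations per BFGS run (default 10000).
#' @param max_restarts maximum BFGS restarts (default 40).
#' @param p_start flat starting value for the registration probabilities
#'   and the inflation factor used in the moment start for `h` (default 0.1).
#' @param weak_min_count cohorts contributing fewer observed registrations
#'   than this are flagged weakly identified in summaries (default 5).
#' @return A list of settings.
#' @export
bc_control <- function(reltol = 1e-9, maxit = 10000L, max_restarts = 40L,
                       p_start = 0.1, weak_min_count = 5) {
  stopifnot(reltol > 0, maxit >= 1, max_restarts >= 1, p_start > 0, p_start < 1)
  list(reltol = reltol, maxit = as.integer(maxit),
       max_restarts = as.integer(max_restarts), p_start = p_start,
       weak_min_count = weak_min_count)
}

#' Maximum-likelihood back-calculation fit
#'
#' Maximises the Poisson deconvolution log-likelihood (see
#' [log_likelihood()]) over the yearly incidence `h_t` (every grid year)
#' and the yearly registration probabilities `p_t` (observation-window
#' years), with pre-observation `p_t` filled by the flat-plus-ramp rule
#' linked to the current estimate at the window's first year.  The leaving
#' rates `q_t` are taken as known from `leaving`.
#'
#' @section Identifiability:
#' With yearly-free `h` and `p` the expected counts factorise over the
#' observable cells as `mu_ij = w_ij * g_i * b_j` (a cohort effect times a
#' registration-year effect with known weights), so the likelihood is
#' exactly invariant under the rescaling `g -> c g`, `b -> b / c`: the
#' data determine the parameters only up to a one-dimensional family
#' trading overall incidence against overall registration probability
#' (see [ridge_shift()], which implements the family in closed form).
#' The maximum of the likelihood is therefore a flat ridge, and any single
#' reported `(h, p)` requires a convention for choosing a point on it.
#'
#' With the default `identify = "smooth"` the fit first locates the ridge
#' and then reports the maximiser whose registration-probability series is
#' smoothest on the log scale (minimal sum of squared second differences
#' of `log p_t` over the window), subject to `p` at the link year not
#' falling below the rule's flat level.  This selection does not change
#' the attained log-likelihood; it only resolves the documented
#' indeterminacy, preferring a registration hazard that evolves gradually
#' — the same kind of regularity the pre-observation ramp already assumes.
#' `identify = "none"` reports the raw optimiser endpoint, an arbitrary
#' ridge point: then only ridge-invariant outputs (fitted `mu`, goodness
#' of fit, lag distributions) should be interpreted.
#'
#' Optimisation is quasi-Newton (BFGS, restarted) with analytic gradients
#' on smoothly reparameterised coordinates: `log h_t` enforces
#' `h_t >= 0` and a scaled logit keeps every `p_t` (including the values
#' induced for pre-observation years) strictly inside `(0, 1 - q_t)`, so
#' the survival factors stay positive.
#'
#' @param counts a [count_matrix()] with at least one positive cell.
#' @param leaving a [leaving_schedule()] on the same grid.
#' @param rule a [pre_obs_rule()]; ignored when the grid has no
#'   pre-observation years.
#' @param start optional list with components `h` (per grid year) and `p`
#'   (per observation-window year) overriding the default moment start.
#' @param fixed_p optional known registration probabilities for the
#'   observation window (scalar or one per window year); when given, only
#'   `h` is estimated.
#' @param link `"simultaneous"` evaluates the ramp linkage inside the
#'   objective at every iteration (the self-consistent reading);
#'   `"two_stage"` first fits with pre-observation `p` frozen at the rule
#'   applied to the starting value, then refreezes the ramp at the
#'   first-stage estimate and refits.
#' @param identify `"smooth"` (default) or `"none"`, see Identifiability.
#' @param control a [bc_control()] list.
#' @return An object of class `"backcalc"` with components `params`
#'   (fitted [parameter_vector()]), `loglik`, `converged`, `n_iterations`,
#'   `mu_hat` (fitted [expected_counts()]), `counts`, `leaving`, `rule`,
#'   `settings`, `identify` (the identification actually applied) and
#'   per-cohort identifiability information; see [summary.backcalc()].
#' @examples
#' g <- year_grid(2000, 2000, 2005)
#' lv <- leaving_schedule(g, mortality = 0.014, cessation = 0.04)
#' truth <- parameter_vector(g, h = 800, p = 0.2)
#' rec <- simulate_careers(sim_spec(g, truth, lv, seed = 1))
#' fit <- backcalc(aggregate_records(rec, g), lv, fixed_p = 0.2)
#' coef(fit)
#' @export
backcalc <- function(counts, leaving, rule = pre_obs_rule(), start = NULL,
                     fixed_p = NULL, link = c("simultaneous", "two_stage"),
                     identify = c("smooth", "none"), control = bc_control()) {
  stopifnot(inherits(counts, "count_matrix"), inherits(leaving, "leaving_schedule"))
  grid <- attr(counts, "grid")
  check_same_grid(grid, leaving$grid)
  link <- match.arg(link)
  identify <- match.arg(identify)
  if (sum(observed_cells_sum(counts)) == 0)
    stop("all observed counts are zero: nothing to fit", call. = FALSE)

  if (link == "two_stage" && is.null(fixed_p) &&
      grid$first_obs_year > grid$first_onset_year) {
    stage1 <- backcalc_engine(counts, leaving, rule, start, fixed_p,
                              control, freeze_link_at = control$p_start)
    p_link_hat <- stage1$params$p[year_index(grid, grid$first_obs_year)]
    fit <- backcalc_engine(counts, leaving, rule, start, fixed_p,
                           control, freeze_link_at = p_link_hat)
  } else {
    fit <- backcalc_engine(counts, leaving, rule, start, fixed_p, control)
  }
  fit$link <- link
  if (identify == "smooth") fit <- ridge_select(fit) else fit$identify <- "none"
  fit
}

# freeze_link_at: NULL for in-objective linkage; a probability to freeze the
# pre-observation ramp at rule(freeze_link_at) (two-stage variant).
# frozen_pre: explicit pre-observation p values overriding the rule entirely
# (used by the independent-draw bootstrap mode).
backcalc_engine <- function(counts, leaving, rule, start, fixed_p,
                            control, freeze_link_at = NULL, frozen_pre = NULL) {
  grid <- attr(counts, "grid")
  n <- n_years(grid)
  yrs <- grid_years(grid)
  q <- leaving$q
  obs0 <- year_index(grid, grid$first_obs_year)   # first window year index
  obs_idx <- obs0:n
  n_pre <- obs0 - 1L
  n_obs <- length(obs_idx)

  cells <- model_cells(grid, observed_only = TRUE)
  ci <- cells$i; cj <- cells$j
  N <- counts[cbind(ci, cj)]
  lw <- ifelse(ci == cj, log(0.5), 0)
  upper <- which(cj > ci)

  estimate_p <- is.null(fixed_p)
  if (!estimate_p) {
    fixed_p <- if (length(fixed_p) == 1L) rep(fixed_p, n_obs) else fixed_p
    if (length(fixed_p) != n_obs)
      stop("fixed_p must have one value per observation-window year", call. = FALSE)
    if (any(fixed_p <= 0) || any(fixed_p >= 1 - q[obs_idx]))
      stop("fixed_p must satisfy 0 < p < 1 - q", call. = FALSE)
  }

  # full p vector as the affine map  p = a + W %*% p_free , where p_free
  # holds the estimated window years and the map carries the
  # pre-observation rule (flat + ramp linked to the first window year)
  p_pre_frozen <- NULL
  if (estimate_p) {
    nf <- n_obs
    a <- numeric(n)
    W <- matrix(0, n, nf)
    W[cbind(obs_idx, seq_len(nf))] <- 1
    if (n_pre > 0L) {
      if (!is.null(frozen_pre)) {
        stopifnot(length(frozen_pre) == n_pre)
        if (any(frozen_pre <= 0) || any(frozen_pre + q[seq_len(n_pre)] >= 1))
          stop("frozen pre-observation p leaves no survival mass", call. = FALSE)
        a[seq_len(n_pre)] <- p_pre_frozen <- as.numeric(frozen_pre)
      } else {
        rr <- resolve_rule(rule, grid)
        wpre <- pre_obs_weights(rr, yrs[seq_len(n_pre)])
        if (!is.null(freeze_link_at)) {
          a[seq_len(n_pre)] <- p_pre_frozen <-
            rr$flat_value * (1 - wpre) + freeze_link_at * wpre
        } else {
          a[seq_len(n_pre)] <- rr$flat_value * (1 - wpre)
          W[seq_len(n_pre), 1L] <- wpre
        }
      }
    }
    # box for each free parameter keeping every induced p_t in (0, 1 - q_t)
    lo <- rep(0, nf); hi <- 1 - q[obs_idx]
    for (kk in seq_len(nf)) {
      dep <- which(W[, kk] != 0 & seq_len(n) != obs_idx[kk])
      for (m in dep) {
        w <- W[m, kk]
        hi[kk] <- min(hi[kk], (1 - q[m] - a[m]) / w)
        if (a[m] < 0) lo[kk] <- max(lo[kk], -a[m] / w)
      }
    }
    const_pre <- seq_len(n_pre)[rowSums(W[seq_len(n_pre), , drop = FALSE] != 0) == 0]
    if (any(a[const_pre] + q[const_pre] >= 1) || any(a[const_pre] <= 0))
      stop("pre-observation rule and leaving schedule leave no survival mass",
           call. = FALSE)
    if (any(hi <= lo))
      stop("pre-observation rule and leaving schedule leave no survival mass",
           call. = FALSE)
    # strict interior margins so survival factors and p stay positive under
    # floating-point saturation of the logistic map
    span0 <- hi - lo
    hi <- lo + span0 * (1 - 1e-8)
    lo <- lo + span0 * 1e-10
    span <- hi - lo
  } else {
    nf <- 0L
    a <- numeric(n); a[obs_idx] <- fixed_p
    if (n_pre > 0L) {
      if (!is.null(frozen_pre)) {
        a[seq_len(n_pre)] <- p_pre_frozen <- as.numeric(frozen_pre)
      } else {
        rr <- resolve_rule(rule, grid)
        wpre <- pre_obs_weights(rr, yrs[seq_len(n_pre)])
        a[seq_len(n_pre)] <- rr$flat_value * (1 - wpre) + fixed_p[1L] * wpre
      }
    }
    if (any(a[seq_len(n_pre)] + q[seq_len(n_pre)] >= 1))
      stop("pre-observation rule and leaving schedule leave no survival mass",
           call. = FALSE)
    W <- matrix(0, n, 0L)
  }

  # moment start: observed registrations attributed to their onset year,
  # inflated by 1 / p_start
  rowN <- numeric(n)
  rs <- rowsum(N, ci)
  rowN[as.integer(rownames(rs))] <- rs
  h0 <- pmax(rowN, 0.5) / control$p_start
  p0_obs <- rep(control$p_start, n_obs)
  if (!is.null(start)) {
    if (!is.null(start$h)) h0 <- grid_series(start$h, grid, "start$h")
    if (!is.null(start$p)) {
      p0_obs <- if (length(start$p) == 1L) rep(start$p, n_obs) else start$p
      if (length(p0_obs) != n_obs)
        stop("start$p must have one value per observation-window year", call. = FALSE)
    }
  }
  if (any(h0 <= 0)) stop("starting h must be positive", call. = FALSE)

  if (estimate_p) {
    p0 <- pmin(pmax(p0_obs, lo + span * 1e-4), hi - span * 1e-4)
    theta0 <- c(log(h0), stats::qlogis((p0 - lo) / span))
  } else {
    theta0 <- log(h0)
  }

  # log-likelihood and analytic gradient in the unconstrained coordinates
  eval_model <- function(theta) {
    lh <- theta[seq_len(n)]
    p_free <- if (nf > 0L) lo + span * stats::plogis(theta[n + seq_len(nf)]) else numeric(0)
    p <- as.vector(a + W %*% p_free)
    r <- 1 - p - q
    cl <- c(0, cumsum(log(r)))                     # cl[k + 1] = sum_{m<=k} log r_m
    lmu <- lw + lh[ci] + (cl[cj] - cl[ci]) + log(p[cj])
    mu <- exp(lmu)
    ll <- sum(N * lmu) - sum(mu)

    A <- N - mu
    gh <- numeric(n)
    rs <- rowsum(A, ci)
    gh[as.integer(rownames(rs))] <- rs
    grad <- gh
    if (nf > 0L) {
      colA <- numeric(n)
      cs <- rowsum(A, cj)
      colA[as.integer(rownames(cs))] <- cs
      # Tm = sum of A over cells whose survival product includes year m
      addv <- numeric(n); subv <- numeric(n)
      if (length(upper)) {
        au <- rowsum(A[upper], ci[upper])
        addv[as.integer(rownames(au))] <- au
        su <- rowsum(A[upper], cj[upper])
        subv[as.integer(rownames(su))] <- su
      }
      Tm <- cumsum(addv) - cumsum(subv)
      g_full <- colA / p - Tm / r
      g_full[p == 0] <- 0
      g_free <- as.vector(crossprod(W, g_full))
      gpsi <- g_free * (p_free - lo) * (hi - p_free) / span
      grad <- c(grad, gpsi)
    }
    list(ll = ll, grad = grad)
  }

  cache <- new.env(parent = emptyenv())
  get_eval <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) return(cache$val)
    v <- eval_model(theta)
    cache$theta <- theta; cache$val <- v
    v
  }

  # restarted BFGS: a single run stalls in the long curved valley of this
  # likelihood; restarting with a fresh Hessian approximation until the
  # objective stops improving reaches the optimum reliably
  theta <- theta0
  ll_prev <- -Inf
  total_iter <- 0L
  conv_ok <- FALSE
  for (round in seq_len(control$max_restarts)) {
    opt <- stats::optim(theta,
                        fn = function(th) get_eval(th)$ll,
                        gr = function(th) get_eval(th)$grad,
                        method = "BFGS",
                        control = list(fnscale = -1, maxit = control$maxit,
                                       reltol = control$reltol))
    theta <- opt$par
    total_iter <- total_iter + unname(opt$counts["gradient"])
    if (opt$value - ll_prev < control$reltol * (1 + abs(opt$value)) &&
        opt$convergence == 0L) {
      conv_ok <- TRUE
      break
    }
    ll_prev <- opt$value
  }

  h_hat <- exp(theta[seq_len(n)])
  p_free_hat <- if (nf > 0L) lo + span * stats::plogis(theta[n + seq_len(nf)]) else numeric(0)
  p_hat <- as.vector(a + W %*% p_free_hat)
  grad_final <- get_eval(theta)$grad

  params <- parameter_vector(grid, h_hat, p_hat)
  mu_hat <- expected_counts(params, leaving)
  loglik <- log_likelihood(counts, mu_hat)
  if (abs(loglik - opt$value) > 1e-6 * (1 + abs(loglik)))
    stop("internal inconsistency: reported log-likelihood does not recompute")

  fit <- structure(list(
    params = params, loglik = loglik,
    converged = conv_ok,
    n_iterations = total_iter,
    mu_hat = mu_hat, counts = counts, leaving = leaving, rule = rule,
    fixed_p = if (!estimate_p) fixed_p,
    p_pre_frozen = p_pre_frozen,
    identify = "none",
    settings = control,
    max_abs_gradient = max(abs(grad_final)),
    cohort_observed = stats::setNames(rowN, yrs),
    cohort_cells = stats::setNames(tabulate(ci, nbins = n), yrs),
    scenario = leaving$scenario,
    grid = grid), class = "backcalc")
  if (!fit$converged)
    warning("optimiser did not converge; best found returned", call. = FALSE)
  fit
}
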