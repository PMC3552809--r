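# msbackcalc

Multi-state back-calculation of hidden-onset incidence from
first-registration records.

## The problem

Many onset processes are never observed directly. The motivating case is
heroin use: nobody registers the year a person starts using, but treatment
registers record the year of *first treatment ever*, together with the
self-reported year of onset. Registers also open late — in the Spanish
setting that motivates the package, onsets span 1971–2006 while first
treatments are observable only from 1991 — so early registrations are
invisible (right truncation), and many users die or quit for good before
ever reaching treatment.

`msbackcalc` estimates the yearly number of new users from such data with a
three-state model:

```
            h_t                p_t
  (outside) ──► 1 active user ──► 2 first registration
                      │ q_t
                      ▼
                3 left before registration (death / lasting cessation)
```

New users enter state 1 as a Poisson stream with yearly expectation `h_t`.
An active user registers for the first time in year `t` with probability
`p_t` (assumed independent of when they started) or exits with probability
`q_t`, the sum of yearly mortality and lasting-cessation rates, which is
supplied as an assumption. Writing `N_ij` for the number of people with
onset in year `i` and first registration in year `j`, each `N_ij` is
Poisson with mean

```
mu_ij = h_i · ∏_{k=i..j-1} (1 − p_k − q_k) · p_j        (j > i)
mu_ii = 0.5 · h_i · p_i                                  (same-year onset:
                                                          about half a year
                                                          of exposure)
```

and the log-likelihood over the observable cells,
`Σ (N_ij log mu_ij − mu_ij)`, is maximised over all yearly `h_t` and the
observation-window `p_t`. Pre-window registration probabilities follow a
flat-plus-ramp rule (0.01 while no treatment was on offer, then a linear
rise linked to the first estimated year's `p`).

Two things the package handles explicitly, beyond the classical method:

* **Identifiability.** With yearly-free `h` and `p` the expected counts
  factorise as a weighted product of a cohort effect and a
  registration-year effect, so the likelihood has an *exactly flat*
  one-dimensional ridge: overall incidence can be traded against overall
  registration probability without changing any observable expectation.
  `ridge_shift()` implements this family in closed form; the default fit
  resolves it with a stated convention (the maximiser whose log
  registration-hazard series is smoothest). See the methods vignette.
* **Validation.** A career-level simulator (`simulate_careers()`)
  generates individual trajectories under known parameters with the exact
  onset-year convention of the formula above, so estimator and simulator
  can be checked against each other cell by cell.

## Worked example

Simulate a register from a reduced-scale synthetic epidemic (onsets
1971–2006, treatments observable 1991–2006), fit, and attach bootstrap
uncertainty:

```r
library(msbackcalc)

spec    <- synthetic_epidemic_spec(h_scale = 0.2, seed = 42)
records <- observed_records(simulate_careers(spec))
counts  <- aggregate_records(records)
leaving <- leaving_schedule(spec$grid, mortality_curve(spec$grid),
                            cessation = 0.04)

fit <- backcalc(counts, leaving, rule = pre_obs_rule(flat_until = 1981))
fit
#> Multi-state back-calculation fit
#>   grid: onset 1971-2006, observation window 1991-2006
#>   observed registrations: 4935
#>   log-likelihood: 9454.7959 (converged, 61 gradient evaluations)
#>   estimated incidence: total 14608.8, peak 1007.0 in 1985

round(coef(fit)[as.character(1989:1993), ], 3)
#>            h     p
#> 1989 899.639 0.066
#> 1990 772.758 0.073
#> 1991 632.246 0.080
#> 1992 598.293 0.098
#> 1993 508.688 0.097

boot <- bc_bootstrap(fit, records = records, n_resamples = 200, seed = 1)
round(subset(summary(boot, pop = synthetic_population(spec$grid)),
             year %in% 1985:1987), 3)
#>      year    h_hat    h_lo     h_hi p_hat  p_lo  p_hi  rate rate_lo rate_hi
#> 1985 1985 1007.035 810.913 1305.363 0.038 0.030 0.054 0.104   0.084   0.135
#> 1986 1986  966.613 785.477 1244.638 0.045 0.037 0.059 0.099   0.081   0.128
#> 1987 1987  968.889 795.591 1217.623 0.052 0.044 0.065 0.098   0.081   0.124
```

Reading the output: the register only opens in 1991, yet the fit places the
incidence peak around 1985 — onset cohorts from the mid-eighties dominate
the early-nineties first registrations once survival through `q_t` is
accounted for. `h_hat` is new users per year, `p_hat` the yearly
probability that an active user registers for the first time (estimated
from 1991, rule-filled before), `rate` converts to new users per 1,000
population, and the `_lo`/`_hi` columns are 95% percentile bootstrap
bounds that combine case resampling with gamma perturbation of the assumed
pre-window registration level and cessation rate.

Diagnostics mirror the method's standard checks: `gof_cohort_curves()`
overlays observed and expected registrations by onset cohort with
per-cohort Poisson deviances, `lag_distributions()` compares observed and
expected onset-to-registration lag distributions, and `run_sensitivity()`
refits under the four standard cessation/mortality scenarios.

There is also a thin command-line front end:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","msbackcalc",package="msbackcalc"))') \
  fit --records records.tsv --out results/run1
```

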