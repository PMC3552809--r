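---
title: "Back-calculating hidden onset incidence from first-registration records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Back-calculating hidden onset incidence from first-registration records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msbackcalc)
```

## The model

The package estimates the yearly incidence of an onset process that is
never observed directly — the motivating application is starting heroin
use — from records of a later first registration event (first treatment
ever), observed only inside a limited window. Three states describe a
career: active consumer (state 1), first registration (state 2, absorbing
for our purposes: later treatments are ignored), and leaving before any
registration through death or lasting cessation (state 3).

Time is discrete in whole calendar years on a `year_grid()`. Entries to
state 1 in year $t$ are Poisson with expectation $h_t$ (persons/year). An
active user in year $t$ registers with probability $p_t$ — assumed the
same whatever year their use began — or exits with probability
$q_t = \text{mortality}_t + \text{cessation}_t$, which the estimator
treats as known. Writing $N_{ij}$ for the count of individuals with onset
in year $i$ and first registration in year $j$, each $N_{ij}$ is Poisson
with mean

$$\mu_{ij} \;=\; h_i \prod_{k=i}^{j-1} (1 - p_k - q_k)\; p_j
\qquad (j > i),$$

the product of expected onsets, survival as an unregistered active user
through years $i,\dots,j-1$, and registration in year $j$. Onset part-way
through a year leaves on average about half a year of exposure, so the
same-year cell is half-weighted: $\mu_{ii} = \tfrac12 h_i p_i$. The
log-likelihood is the Poisson deconvolution form

$$\ell \;=\; \sum_{(i,j)\ \text{observable}} \left( N_{ij}\log\mu_{ij} -
\mu_{ij} \right),$$

dropping the $\log N_{ij}!$ term, which depends only on the data and so
shifts $\ell$ by a constant that affects neither the maximiser nor
likelihood comparisons on fixed data. The sum runs over cells with
$i \le j$ and $j$ inside the observation window
$[\text{first\_obs\_year}, \text{last\_year}]$ — the only cell domain
consistent with a register that opens late (right truncation). No
"no-event-yet" term for registrations after the study's end is included:
the likelihood contains observed cells only, and we flag rather than
guess beyond that form. Cells with $N_{ij}=0$ and $\mu_{ij}=0$ contribute
exactly $0$ (the continuous extension of $0\log 0$); a positive count on
a zero expectation is reported as an error naming the offending cell.

## Assumption schedules

**Leaving rates.** Only fragments of the mortality history of active
users are usually known. `mortality_curve()` linearly interpolates a
small anchor set and extrapolates constantly outside it; the shipped
default encodes the values available for the Spanish epidemic — 1.0% in
1971 rising to the 1.4% minimum at 1984/1985, the 6.6% maximum in 1995,
1.5% in 1999 and 1.0% by 2006. Between the published minimum and maximum
the true cohort series may well have moved non-monotonically; linear
interpolation is the minimal assumption and every fit records the full
schedule used, so a better series can be substituted directly
(`read_schedule()`). For analyses split by route of administration the
same mortality is used for injectors and a constant 1% for non-injectors;
stratified fits are simply two independent runs on the stratified count
matrices.

**Cessation** is a constant yearly rate; published long-term cohort
reviews bracket it at 0.02–0.04. `sensitivity_scenarios()` crosses those
two values with a mortality offset of 0 or +0.01 (guarding against
under-recorded out-of-treatment mortality), giving the four standard
leaving-rate combinations; the unmodified-mortality, cessation-0.04
combination is the primary analysis and `run_sensitivity()` refits all
four.

**Registration before the window.** $p_t$ can only be estimated inside
the window. Earlier years follow `pre_obs_rule()`: a flat low level
(default 0.01 — essentially no dedicated treatment on offer) through
`flat_until`, then a linear ramp up to the *estimated* $p$ at the
window's first year. The linkage is evaluated inside the objective at
every iteration, so the ramp always ends at the current estimate — the
only self-consistent reading; a literal two-stage variant (fit, freeze
the ramp at the first-stage estimate, refit) is available via
`link = "two_stage"` for comparison. On a generic grid `flat_until`
defaults to the midpoint of the pre-observation span, which reproduces
the canonical 1981 on a 1971/1991 grid.

## Identifiability: an exactly flat likelihood ridge

This is the methodological point the package is most explicit about.
Define, relative to the window start $o$,

$$A_j = \prod_{k=o}^{j-1} (1 - p_k - q_k), \qquad b_j = A_j\,p_j,
\qquad g_i = \begin{cases} h_i / A_i & i \ge o\\
h_i \prod_{k=i}^{o-1}(1-p_k-q_k) & i < o.\end{cases}$$

Every observable expectation factorises as
$\mu_{ij} = w_{ij}\, g_i\, b_j$ with known weights
($w_{ij} = \tfrac12$ on the diagonal, 1 elsewhere). A rescaling
$g \to c\,g$, $b \to b/c$ therefore leaves *every* observable $\mu_{ij}$,
and hence the likelihood, exactly unchanged. The transformed
probabilities are recovered from the forced recursion
$A'_{j+1} = A'_j(1-q_j) - b'_j$, $p'_j = b'_j/A'_j$, and incidence
absorbs the complementary factors — including the re-linked
pre-observation ramp, whose effect on early cohorts is a per-cohort
scale that free $h_i$ absorbs. `ridge_shift()` implements this family in
closed form, and the test suite freezes it as a property: shifted fits
differ substantially in $(h, p)$ yet reproduce the log-likelihood to
numerical precision.

The consequence: yearly-free $h$ and $p$ with known $q$ are identified
only up to this one-dimensional family. Any single reported parameter
set requires a convention for choosing a point on the ridge, and any
implementation that reports one (the original analyses included)
implicitly uses whatever convention its optimiser and starting values
induce. We make the convention explicit. With the default
`identify = "smooth"`, `backcalc()` first maximises the likelihood, then
slides along the ridge to the maximiser whose window
registration-probability series is smoothest on the log scale
(minimal $\sum (\Delta^2 \log p_t)^2$), subject to $p$ at the link year
not falling below the rule's flat level. Raw-scale roughness would be
degenerate — as $c \to \infty$, $p \to 0$ uniformly, which is perfectly
smooth — while log-scale roughness has a well-defined interior minimum,
because sliding the ridge bends the late-window hazard sharply. The
selection changes nothing the data can check (the attained
log-likelihood is asserted unchanged to $10^{-6}$ relative); it encodes
the same kind of regularity belief as the pre-observation ramp itself: a
registration hazard that evolves gradually rather than kinking. With
`identify = "none"` the raw optimiser endpoint is returned, and only
ridge-invariant outputs — fitted expectations, deviances, lag
distributions — should be interpreted.

Two further consequences are worth stating. First, an independent
brute-force search of the same objective can be expected to agree with
the optimiser in log-likelihood but *not* in parameters — both land on
the same flat manifold at arbitrary points — and the acceptance test for
the optimiser is phrased accordingly. Second, simulation-based
validation is only meaningful when the generating truth itself satisfies
the selection convention; the shipped synthetic epidemic (below) is
constructed that way.

## Optimisation

Constraints are handled by smooth reparameterisation: $\log h_t$ for
$h_t \ge 0$, and a scaled logit mapping each estimated $p_t$ into
$(0,\, 1-q_t)$ so survival factors stay positive; the bound on the
link-year parameter is additionally tightened so that every ramp-induced
pre-observation value also keeps positive survival mass. The full $p$
vector is an affine map of the free parameters (intercepts carry the
flat segment, a weight matrix carries the ramp linkage), which makes the
analytic gradient a single transpose-multiply: per-cell residuals
$N-\mu$ are accumulated into per-year row sums (for $\log h$), per-year
column sums (the $p_j$ factor) and an interval sum via cumulative
differences (the survival factors).

The maximiser is BFGS. A single run stalls in this likelihood's long
curved valley — the relative-improvement stop triggers while far from
the optimum — so the optimiser is restarted with a fresh Hessian
approximation until an extra run improves the log-likelihood by less
than `reltol` (default $10^{-9}$ relative, at most 10,000 iterations per
run and 40 restarts; all reported in the fit object together with the
final gradient norm). Starting values are a moment start: observed
registrations attributed to their onset cohort and inflated by
$1/p^{(0)}$ with $p^{(0)} = 0.1$ flat. With the smooth identification the
optimum reported is start-independent (a frozen test refits from
dispersed random starts and requires agreement to 1% in parameters and
$10^{-6}$ in log-likelihood).

Cohorts near the end of the grid are informed by very few cells — the
final onset year only by its half-weighted diagonal cell — and no
smoothing or penalty is added to hide that; `summary()` flags cohorts
with fewer than `weak_min_count` observed registrations or at most two
observable cells, and the bootstrap bands widen accordingly.

## Uncertainty

`bc_bootstrap()` implements a two-part scheme per replicate: (1) the
observed records are resampled with replacement (given only an aggregated
matrix, observed cells are resampled multinomially with the total fixed
— for records carrying no fields beyond their cell this induces the same
distribution); (2) the assumed quantities are perturbed by gamma draws
with shape and scale moment-matched to mean = assumed value and sd =
`assumption_sd` (default 0.01): one draw for the flat pre-observation
registration level, with the ramp re-linked inside each replicate's
refit, and one draw applied to the cessation rate of every year (the
assumed cessation is a single constant; a non-constant series is shifted
by the draw minus its mean). Mortality is not perturbed. The two phases
consume separate stretches of the RNG stream, so runs at matched seeds
share identical resamples whatever the perturbation settings —
disabling the perturbation is comparable replicate by replicate.
Pre-observation values can instead be drawn independently per year
around the point-estimate rule values (`pre_obs_mode = "independent"`),
frozen within the replicate; the level-plus-ramp default reflects that
ramp years are defined by interpolation, not independent guesses.

Intervals are percentile bounds across converged replicates (the
flagship analysis uses 500 replicates and 95% bands); replicates that
fail to converge are counted and excluded rather than retried, keeping
the replicate set i.i.d. Rate conversion (`to_rates()`, per 1,000
population) is applied to each replicate before taking percentiles —
order-preserving for fixed denominators, so equivalent to converting the
bounds. No Hessian-based standard errors are offered: the ridge makes
curvature-based uncertainty for individual parameters meaningless.

## The career simulator

`simulate_careers()` draws whole careers: $M_i \sim
\text{Pois}(h_i)$ onsets per year, then per year a competing choice
between registration, exit and staying. The onset year needs a
convention, because the formula above half-weights the diagonal cell
while using full-year survival $(1-p_i-q_i)$ in later cells — an
internal tension of the model itself. The default `"matched"` convention
resolves it in favour of exact agreement with the expected-count
formula in *every* cell: treated $\tfrac12 p_i$, stayed $1-p_i-q_i$,
exited the residual $q_i + \tfrac12 p_i$. The `"naive"` alternative
(treated $\tfrac12 p_i$, exited $q_i$, stayed the rest) looks more
natural but over-weights survival relative to the formula for $j>i$; it
is provided behind a flag and documented as inconsistent. A
Monte-Carlo acceptance test holds empirical cell means over 5,000
replicates within four standard errors of $\mu_{ij}$ in every cell under
the matched convention. Exit causes are split death/cessation in
proportion to the schedule components (cosmetic; the estimator never
sees them), and an optional corruption rounds reported onset years to
the nearest year ending in 0 or 5, mimicking digit preference in
self-reported onset — off by default and never corrected for.

`synthetic_epidemic_spec()` packages the flagship validation design: a
1971–2006 onset grid observed from 1991, Gaussian-shaped incidence
peaking at 5,000/year in 1986, the default mortality curve with
cessation 0.04, and a registration hazard that follows the
pre-observation rule (flat 0.01 through 1981, ramp to 0.08 at 1991) and
then rises smoothly to 0.30 by 2006 — quadratic in lag with initial
slope equal to the ramp slope, so the truth satisfies the smooth
identification convention and recovery is a well-posed question. Every
number is synthetic, chosen for shape realism; none is estimated from
any register. What the simulator does *not* emulate: age structure,
within-year timing, relapse and re-treatment, reporting error other than
the optional onset rounding, and registration probabilities that depend
on onset era. Passing recovery tests on these data therefore shows the
estimator inverts its own model faithfully at realistic scale — not that
the model captures every feature of real registers.

## Problem sizes and numerical choices

The test suite exercises: the flagship 36-year design at its stated
scale for one-shot recovery; a 10-year toy (three pre-observation years,
$h = 1000$/year, geometric window hazard) for bootstrap coverage, with
200 replicates inside each of 50 outer simulations; a 20-year fully
observed grid for deviance calibration over 20 replicates; and a 3-year
toy for the brute-force likelihood search (three-dimensional grid with
incidence profiled out in closed form, refined to a $5\times10^{-4}$
step). These sizes were chosen so each check has the statistical
resolution its tolerance needs while the whole suite stays quick to run.

Numerical details worth knowing: probabilities are kept strictly inside
their boxes by relative margins ($10^{-8}$ at the top, $10^{-10}$ at the
bottom of each logit scale) so survival factors never round to zero or
negative values; duplicate cells in long-format input are accumulated,
not overwritten; percentile bounds use the default type-7 empirical
quantile; the ridge-selection scale is located on a 301-point
logarithmic grid over $c \in [0.05, 50]$ and polished by golden-section
search, with infeasible scales given a large finite sentinel value.

## Limitations

The leaving rates are assumptions, not estimates, and everything scales
with them — the sensitivity scenarios bound but do not remove that
dependence. The identification convention is exactly that: a convention;
two conventions can disagree about the split between incidence level and
registration probability while fitting the data identically, so
comparisons across studies should compare ridge-invariant quantities or
state their conventions. Late-grid cohorts are weakly identified by
construction. The model has no age structure and assumes registration
probability independent of onset era; violations bias results in
directions that cannot be determined from register data alone.
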