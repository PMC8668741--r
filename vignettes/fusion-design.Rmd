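---
title: "The fusion design: offsetting carcass counts with flight intensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fusion design: offsetting carcass counts with flight intensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusiondesign)
```

## The problem

Bird flight diverters are visual markers attached to power lines to reduce
bird collisions. Their effectiveness is usually estimated from carcass
searches below marked and unmarked lines. The standard design is
before-after control-impact (BACI): two sites are searched in two periods,
diverters are installed at the impact site between the periods, and the
period-by-site interaction of a count model estimates the effect. BACI is
only unbiased under the *synchronicity assumption*: relative changes in
bird flight intensity from one period to the next must be the same at both
sites. Flight surveys show this assumption often fails, and when it fails
the BACI estimate absorbs the differential change in flight activity.

The *fusion design* drops the control site and instead measures flight
intensity directly at the treated line. Carcass counts are related to the
concurrently observed number of crossing birds, so the period contrast
becomes a collision-*rate* ratio and extrinsic fluctuations in flight
activity cancel by construction.

## Models

All estimators act on tabular survey data: one row per carcass search
(corrected, possibly non-integer carcass count; search interval length;
site; period) and one row per flight-observation session (individuals
counted, hours observed).

**BACI** (`fit_baci()`): negative binomial GLM, log link,

$$\log E[N_i] = b + \beta_P\,\mathrm{period}_i + \beta_S\,\mathrm{site}_i +
\beta_{PS}\,\mathrm{period}_i\!\times\!\mathrm{site}_i ,$$

with the estimated collision reduction $100(1 - e^{\beta_{PS}})$ per cent.
**BA** (`fit_ba()`) keeps only the impact site and the period term; it is
mathematically equivalent to a control-impact comparison with sites
relabelled as periods, and is confounded by *any* change in flight
intensity.

**NB fusion** (`fit_nb_fusion()`): for each pair of consecutive carcass
searches at the treated line, the flight sessions falling in the interval
are pooled (`pool_flights()`) into the exposure

$$A = \mathrm{days} \times \mathrm{individuals} / \mathrm{hours},$$

and the model is

$$\log E[N_i] = b + \beta_P\,\mathrm{period}_i + \log(1 + A_i),$$

a negative binomial GLM with a fixed offset. The `1 +` guard keeps
intervals without observed birds ($A = 0$) in the likelihood with a zero
offset; at realistic exposures ($A \sim 10^3$) the difference from
$\log A$ is negligible. The reduction is again $100(1 - e^{\beta_P})$.

**B fusion** (`fit_b_fusion()`): the same comparison cast as a grouped
binomial GLM, with events $\mathrm{round}(c\,N/\mathrm{days})$ and
non-events $\mathrm{round}(c\,\mathrm{individuals}/\mathrm{hours})$ on the
logit scale. Because collisions are orders of magnitude rarer than
crossings, the period odds ratio is practically a rate ratio and the same
back-transform is used.

**Synchronicity test** (`test_synchronicity()`): a negative binomial GLM
of counted individuals on `period + site + period:site` with offset
$\log(\mathrm{hours})$, fitted to flight data alone. The interaction
coefficient $\beta$ measures the violation, and $100(e^{\beta} - 1)$ is
the expected percentage bias of a BACI estimate computed from carcass data
at the same sites.

```{r example, eval = FALSE}
searches <- read_carcass_table("carcass.csv")
flights  <- read_flight_table("flights.csv", species_group = "geese")
obs <- pool_flights(searches, flights, site = "impact")
glance(fit_nb_fusion(obs, seasonal = TRUE))
test_synchronicity(flights)
```

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `theta` (NB dispersion) | variance $= \mu + \mu^2/\theta$ | estimated | profile ML; small $\theta$ = strong overdispersion |
| `c` (B fusion) | rate scaling before rounding | 10 000 | preserves fractional corrected counts; use 1 when rates are already integers |
| `n_basis` | cyclic spline size | 8 | small fixed seasonal basis, unpenalized |
| `level` / `alpha` | CI level / test size | 0.95 / 0.05 | two-sided Wald inference throughout |
| `mu1`, `theta1` | flight-count NB moments | 1254, 0.41 | calibrated to pooled geese flight counts |
| `zeta` | collision probability per observed crossing | 0.001 | carcasses relative to observed crossings |
| `omega`, `gamma` | period-wide and impact-only flight multipliers | 1, 1 | study conditions; ranges [1, 2.5] in comparisons |
| `lambda` | true diverter reduction | 0 | effect sizes 0.1-0.9 in power studies |
| `n_obs_per_cell` | search intervals per site x period | 60 | pooled flight totals divided by `mu1` give about 61 intervals per cell in the motivating data |
| `detect_prob` | fraction of crossings observed | 1 | 0.01 in the partial-detection scenario |

## The simulator

`simulate_dataset()` draws, per site x period cell and interval, a true
flight count $F \sim \mathrm{NB}(\mu, \theta_1)$ (as a gamma-Poisson
mixture, which is numerically robust at $\theta_1 = 0.41$), where $\mu$ is
$\mu_1$ before, $\mu_1\Omega$ after at the control site and
$\mu_1\Omega\Gamma$ after at the impact site; then per-bird collisions
$C \sim \mathrm{Bin}(F, \zeta)$, with $\zeta(1 - \Lambda)$ in the
impact-after cell. $\Gamma > 1$ raises impact-after carcasses and so
*counteracts* the diverter signal in BA/BACI — the adversarial direction.
Under partial detection, the observed count
$O \sim \mathrm{Bin}(F, p_{det})$ is drawn independently of the
collisions and only $O$ is forwarded to the fusion models; collisions use
the true count, so carcass density matches the base scenario.

Each simulated interval spans one day and one observation hour, so the
fusion exposure is simply $A = O$. Deliberately *not* emulated: seasonal
structure (no day-of-year effect is simulated, and the spline is switched
off in simulation fits), heterogeneous search intervals, empty-interval
carry-over (every interval has flight data by construction), temporal
autocorrelation, and carcass-correction uncertainty. Passing simulation
tests therefore validates the estimators' operating characteristics under
idealized survey logistics, not the field-data plumbing, which is
exercised separately on constructed survey tables.

`run_comparison()` fixes or draws $(\Omega, \Gamma, \Lambda)$ per dataset,
fits the requested estimators, and records estimate, p-value and
convergence per dataset x method. A master seed spawns per-dataset
sub-seeds, so runs are reproducible and subsets re-runnable.

## Evaluation conventions

Power counts sign-correct rejections ($p < \alpha$ and estimated
reduction $> 0$); false-positive rates are sign-agnostic. Rates carry
exact binomial Monte Carlo standard errors and Wilson 95% intervals.
`power_ratio()` averages each method's power over the true-reduction grid
$\Lambda \in \{0.1, \dots, 0.9\}$ and takes the ratio.

Two conventions deserve emphasis:

* **Slice versus integrated summaries.** Per-parameter performance curves
  (`performance_curve()`) hold the other parameters at fixed values —
  exact Monte Carlo slices rather than smoothed surfaces. Summary power
  *ratios*, however, are computed with $\Omega, \Gamma$ drawn uniformly
  from $[1, 2.5]$ per dataset: integrating over realistic flight-intensity
  variation is what makes the comparison representative, since BACI's
  power collapses as $\Gamma$ grows while the fusion estimators are flat
  in it; evaluating both methods only at the ideal corner
  $\Omega = \Gamma = 1$ understates the practical difference and is not
  how the comparison is meant to be read.
* **B fusion scaling in simulations.** `run_comparison()` calls
  `fit_b_fusion()` with $c = 1$: simulated rates are already integers, and
  multiplying exact counts by a large $c$ would multiply the nominal
  binomial sample size by $c$ and destroy the test's calibration. The
  large default $c$ exists for real, fractional corrected counts, where it
  trades a negligible variance misstatement for eliminating rounding bias.

## Numerical choices

* NB fitting alternates IRLS for the coefficients with one-dimensional
  profile maximization of the likelihood over $\log\theta$; convergence at
  max-norm coefficient change $< 10^{-8}$ and relative $\theta$ change
  $< 10^{-6}$. The likelihood uses gamma functions, so non-integer
  corrected counts are valid responses.
* $\theta$ is capped at $10^7$; when the profile is flat up to the cap
  (no residual overdispersion) the cap is returned, which pins the
  Poisson limit instead of letting $\theta$ wander.
* Wald (not likelihood-ratio) inference, with the covariance conditional
  on the fitted $\theta$; confidence intervals for the percent reduction
  transform the link-scale endpoints (a monotone map), not the delta
  method.
* The cyclic day-of-year spline is an unpenalized cubic B-spline with
  period 365 (day 366 aliases day 1), equally spaced knots, and value,
  first and second derivative matched at the seam. Next to an intercept
  the centered basis drops one column for identifiability.
* Flight pooling uses half-open intervals (previous search date, search
  date], so a session on a search date belongs to the interval that the
  search closes and nothing is double-attributed. Searches whose interval
  contains no flight session roll their carcasses and days forward into
  the next closed observation.
* Degenerate inputs fail loudly: all-zero responses, empty design cells,
  all-zero exposure, positive counts with zero hours. B fusion rows that
  round to (0, 0) are dropped with a warning. Non-converged fits are
  flagged, and `run_comparison()` records rather than drops them.

## Design decisions

The BA estimator is fitted to the *impact* site: diverters are only ever
installed there, so a before-after contrast is informative about them only
at that site. The acceptance-scale simulation sizes are 1 000-2 000 null
datasets for type-I-error estimates and 200-250 datasets per grid point
for power ratios, with tolerances stated as multiples of the binomial
Monte Carlo standard error; these sizes make the package's own checks
reproducible on a laptop. `n_obs_per_cell = 60` reconstructs the
motivating study's data density (per-cell pooled flight totals divided by
$\mu_1$ give roughly 61 intervals); it is exposed as an ordinary parameter
because other field designs are sparser.

## Limitations

The estimators assume collision events are independent across birds and
intervals given flight intensity; flocking species may violate this and
inflate the effective dispersion. The B fusion model understates its
variance when $c$ inflates fractional rates, and is reported by the
package mainly as a cross-check on the NB fusion model, which converges
more reliably on sparse data and is the recommended estimator. Real-data
seasonal adjustment uses a small unpenalized spline rather than
penalized smoothing, so strongly wiggly seasonal patterns are only
approximated. Uncertainty in upstream carcass-correction factors is not
propagated: corrected counts are treated as observed.
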