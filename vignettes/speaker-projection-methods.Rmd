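---
title: "Probabilistic projection of first-language speaker populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic projection of first-language speaker populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lingcast` projects the number of first-language speakers of small,
endangered languages a century ahead, with uncertainty. Its inputs are the
kind of data national statistical agencies actually publish: speaker counts
by five-year age group from repeated quinquennial censuses (perturbed by
random rounding to base 5 for disclosure control), period life tables, and
age-specific fertility schedules. Its outputs are median speaker-number
trajectories with 80% projection intervals, and dormancy risks -- the
probability that no speakers (of any age, under 50, or under 15) remain by
a given year.

This vignette is the package's own account of the method: the model, its
assumptions, the tunable parameters, what the synthetic-data generator does
and does not emulate, the numerical choices, and the known limitations.
Every empirical statement here is computed by the package's tests or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## The demographic model

A language is treated as a closed, one-sex population: speakers enter by
birth-and-transmission (a child raised in the language) and leave by death.
Migration and language shift during adulthood are assumed negligible; a
person who acquires the language in childhood is assumed to keep it for
life. The model advances the population in five-year age groups over
five-year steps from 2001 to 2101, with a maximum age at death of 100.

Three stages feed one another.

### 1. Probabilistic baseline population in 2001

Five censuses (2001--2021) observe the same birth cohorts at different
ages. Each closed age group at census year $t$ identifies a cohort (its
birth years are $t$ minus the age limits), and the cohorts born 1917--1921
through 1997--2001 are kept: these are observable throughout the census
window within closed age groups. (The oldest cohort reaches the open-ended
100+ group by 2021, so it contributes four usable observations rather than
five; downstream fits simply use the available $n$.)

Counts observed after 2001 are *recast* to 2001 by survivorship inversion:
if $M$ is the cumulative probability of dying between 2001 and $t$
(a product of five-year death probabilities along the cohort's diagonal
through the life table), the mortality-free 2001 equivalent of a count $N$
is $N/(1-M)$. The same algebra run backwards ($N/(1-M)$ with $M$ taken
between an earlier year and 2001) reconstructs the cohort sizes alive in
1981--1996; the two directions are exact inverses, which the tests verify
to $10^{-9}$.

The recast estimates of one language then yield a baseline model with two
error levels:

* **Total size**: the five per-census totals are treated as replicate
  estimates of one quantity; a location-scale t-distribution with location
  $\mu$ (their mean), scale $\tau$ (the standard error of the mean,
  $s/\sqrt{n}$) and $n-1$ degrees of freedom captures the uncertainty of
  the total.
* **Age composition**: each cohort's five estimates get a moment-fitted
  count distribution with quadratic mean--variance law, i.e. a negative
  binomial with mean $\mu_c$ and dispersion $\phi_c = s_c^2/\mu_c^2$
  (variance $\phi_c \mu_c^2$). When the sample variance does not exceed
  the mean no negative binomial exists and a Poisson with the same mean is
  used; an empty cohort is degenerate at zero.

A baseline *draw* realises one total $T$ from the t-distribution
(truncated at zero, rounded) and 17 cohort counts, then rescales the
cohort counts by largest-remainder apportionment so they sum exactly to
$T$. The t-distribution thus owns the total's error, the negative
binomials the shape's error.

### 2. Transmission trends (xTFR)

The mean number of child speakers per adult speaker is estimated
indirectly from each age pyramid with the xTFR estimator,

$$\mathrm{xTFR} = (10.65 - 12.55\,\pi_{25\text{--}34})\cdot C/W,$$

where $C$ counts speakers aged 0--4, $W$ speakers aged 15--49 and
$\pi_{25\text{--}34}$ the share of ages 25--34 within $W$. Because it is
applied to speakers of both genders, replacement sits near **one** child
speaker per adult speaker, not 2.1. Backward-recasting a baseline draw to
1981, 1986, 1991 and 1996 and evaluating the formula (plus on the draw
itself in 2001) gives five transmission estimates per draw.

A trend is fitted to the five points: a decreasing series (negative
least-squares slope) gets ordinary least squares of $\log(\mathrm{xTFR})$
on calendar year (exponential decay); otherwise the model is linear in
$\log(\text{year})$ and constrained through an anchor at 2096 equal to the
1981--2001 mean, which keeps growth bounded. Under the **freeze** scenario
the fitted path runs to 2046 and is held constant thereafter; under
**unlimited** it runs to 2096 unconstrained. Values are floored at zero.

Timing convention: the estimate labelled with census year $y$ measures
births over $(y-5, y]$, and the projected value labelled $t$ governs the
step $(t, t+5]$ -- a consistent half-period convention carried through
estimation and projection.

### 3. Individual-based stochastic projection

Each five-year step applies, individual by individual (realised in
aggregate as exact binomial draws), the age- and period-specific
probability of dying; survivors age five years, and the 95--99 group
always dies (maximum age 100). Expected births are
$B_t = \mathrm{xTFR}_t \sum_a w_a(t)\, n_a(t)$ over the reproductive ages,
so a speaker passing through all reproductive ages accumulates
$\mathrm{xTFR}$ expected children; realised births are Poisson, and
newborns survive into the 0--4 group with probability
$(1-q_{0\text{--}4})^{1/2}$ (constant hazard within the age interval,
half an interval of exposure).

The allocation weights $w_a(t)$ come from a log-normal age pattern of
fertility: the pattern is least-squares fitted to normalised schedule
profiles in 2001 and 2100 (age-group midpoints 17.5 ... 47.5 as
evaluation points), its location and scale interpolated linearly in
calendar year, and the density at the midpoints renormalised into a
proper weight vector.

Every Monte-Carlo replicate redraws the *whole* chain -- baseline draw,
transmission series, trend fit, stochastic trajectory -- so the ensemble
propagates parameter and demographic uncertainty jointly; 3000 replicates
per language is the default. Summaries use empirical medians and the
0.1/0.9 quantiles (inverse-empirical-CDF convention on sorted integer
counts) for 80% projection intervals, and dormancy risk is the percentage
of replicates with zero speakers in an age band.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_reps` | 3000 | Monte-Carlo replicates per language |
| `scenario` | `"freeze"` | transmission path constant after 2046 (`"unlimited"`: fitted trend to 2096) |
| `baseline_year`, `horizon` | 2001, 2101 | projection window (quinquennial) |
| `freeze_year`, `anchor_year` | 2046, 2096 | scenario switch year; anchor of the non-decreasing trend model |
| `eps` (trend fit) | 0.005 | floor before taking logs of transmission values; below the smallest magnitude the estimates resolve |
| totals filter `alpha` | 0.001 | exclusion threshold for implausible census totals |
| cell filter `alpha` | 0.01 | exclusion threshold for implausible age cells |

## Quality screening

Incomplete enumeration can corrupt single censuses. Two filters run before
baseline fitting.

*Totals*: each census's recast total is compared with the language's other
censuses via a leave-one-out z-score referred to its exact null
distribution under normality (the externally studentized residual,
$z/\sqrt{1+1/m} \sim t_{m-1}$). The include-self alternative is a dead
filter at $n=5$ -- its statistic is bounded by $(n-1)/\sqrt{n} = 1.79$, so
nothing can ever reach the 0.001 level -- and a plain normal reference
over-flags several-fold; the studentized form makes the filter's actual
size equal its nominal size, which the test suite checks by simulation.

*Age cells*: each (cohort, census) estimate is compared with a robust
expectation (median cohort shares times median census levels -- robust so
that a grossly wrong cell cannot mask itself by dragging its own row and
column along), standardised by an estimated quadratic mean--variance law
with the language's robust dispersion, floored at the worst-case noise of
base-5 rounding. In the Poisson regime this reduces to a slightly
conservative Pearson residual; for large overdispersed counts it stays
calibrated where a raw Pearson residual would flag every cell.

Filters never reduce a language below three censuses, nor a cohort below
two estimates.

## The synthetic-data generator

`scenario_spec()` / `make_true_population()` / `simulate_censuses()`
generate census bundles from known ground truth, so every stage is
testable without any real data and parameter recovery can be measured.

The true population follows the deterministic expectation recursion of the
projection model itself, from a 1941 initial pyramid, with transmission
clamped to its 1981 value before 1981 (a burn-in that makes the 1981 age
structure dynamically consistent with the stated trajectory). Because the
recursion is linear in the initial counts, each preset's true 2001 size is
calibrated exactly by rescaling. Census observation error is negative
binomial with variance $\phi\,\mu^2$ ($\phi = 0.005$ by default, i.e. a
7% coefficient of variation -- the scale of coverage error one expects for
small populations enumerated with weighting and rounding), floored at
Poisson noise where the quadratic law would fall below it, followed by
unbiased random rounding to base 5 (round up with probability
remainder/5). A `"poisson"` switch generates deliberately misspecified
noise for robustness tests, and `with_undercount()` contaminates chosen
censuses multiplicatively.

Four presets span the qualitative regimes of endangered-language
demography -- large and growing (~6000 speakers, transmission above 1),
large and declining (~80000, sliding below 1), small with transmission
collapsing to zero by 1991 (~700), and tiny near-dormant (~120) -- plus a
27-language bundle cycling these archetypes over log-spaced sizes.

What the generator does **not** emulate: correlated undercount across
consecutive censuses, age-heaping and misreporting, real enumeration
mechanics (weighting, imputation), migration, or adult language shift.
Passing calibration tests on this generator therefore shows the pipeline
is self-consistent, not that real census data satisfy its assumptions.

## Numerical and design choices

* **Recast algebra**: "adding back the dead" is implemented as division by
  cumulative survivorship, $N/(1-M)$ -- the only form consistent under
  composition of periods and exactly invertible (the additive $N(1+M)$ is
  not). A cohort's age within a step is its age-group label at the step's
  start; no within-interval interpolation at quinquennial resolution.
* **t-draws** can be negative or fractional for tiny languages: truncated
  at zero and rounded; largest-remainder apportionment preserves the total
  exactly without systematic bias, ties broken towards younger cohorts.
* **Trend fitting** centres calendar years at 2001 before the log-linear
  regression (numerical hygiene; the fitted curve is unchanged) and uses
  raw calendar years inside $\log(\text{year})$. A slope of exactly zero
  routes to the bounded, mean-anchored model -- as does the rarer corner
  where a series *decreases in value* yet its log-linear fit has a
  positive rate (the floor compresses near-zero values): an exponential
  "decay" model that grows without bound would be self-contradictory, so
  such series also use the anchored model. The 2096 anchor is imposed as
  a hard constraint (fit through the point), the cleanest reading of an
  anchored extrapolation.
* **Degenerate pyramids**: a year with no speakers aged 15--49 gets a
  transmission value of 0 rather than an undefined ratio; an all-zero
  series yields an identically-zero path.
* **Quantiles** of replicate counts use the inverse-empirical-CDF (type 1)
  convention: counts are small integers and interpolation would
  manufacture impossible values.
* **Random numbers**: one master seed; per-language seeds by a fixed
  affine-modular rule, per-replicate sub-seeds drawn once from the
  language seed -- any replicate is reproducible in isolation and results
  do not depend on which other languages are in the run.
* **Dormancy monotonicity** is asserted in code for the all-ages and
  under-50 bands, where dormancy is provably absorbing (no births can
  arise once no speaker is below 50). The under-15 band is *not*
  absorbing -- children can be born again while reproductive-age speakers
  remain -- and its risk curve can dip by a few tenths of a percentage
  point; tests assert near-monotonicity only.

## Validation and problem sizes

The test suite (all sizes chosen as the package's own balance of
statistical power against desk-scale runtime) checks, among others:

* exact hand-computed oracles for the recast, the xTFR formula, the trend
  fits and the quantile conventions;
* ensemble means against an independently coded deterministic expectation
  recursion, per cell, at 400 replicates per preset with a familywise
  z-threshold;
* parameter recovery over 200 simulated census bundles per preset: mean
  absolute error of recovered transmission rates below 0.1, and the true
  ages-0--84 total inside the estimated 80% band in 70--90% of runs;
* calibration: on a four-preset bundle at 3000 replicates, the share of
  synthetic census cells inside the 80% hindcast intervals is within
  3 points of 80% (this is also what `scripts/acceptance.R` recomputes);
* filter calibration: false-flag rates at or below the nominal 0.001/0.01
  under the model's own noise, and ≥95% detection of a census
  undercounted threefold.

## Limitations

* The model is one-sex and closed: no migration, no adult acquisition or
  attrition, no interaction between languages.
* Transmission enters only through the xTFR ratio; the estimator carries a
  half-period timing lag and its linear age-composition correction is an
  approximation, both inherited by the projections.
* Interval coverage on very small populations is conservative by
  discreteness: an 80% interval over counts supported on a handful of
  multiples of five cannot be exact, so pooled hindcast coverage tends to
  run slightly above nominal when tiny languages dominate the cell pool.
* Baseline ages span 0--84 in 2001 (older cohorts are not observable five
  times); speakers 85+ at baseline are outside the model and enter
  trajectories only as later cohorts age.
* Mortality and fertility schedules are taken as known inputs; their own
  uncertainty is not propagated.
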