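---
title: "Methods: age-structured modelling of smoking and lung cancer burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-structured modelling of smoking and lung cancer burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcforecast)
```

## The model

`lcforecast` simulates a closed single-sex population stratified by single
year of age and by smoking history. Four compartments partition the living
population at calendar time $t$ and age $a$: never-smokers $M(t,a)$,
current smokers $S(t,a)$, ex-smokers $E(t,a)$ and people living with
diagnosed lung cancer $L(t,a)$. Transitions are governed by five
nonnegative hazard surfaces, each per person-year:

* $\sigma(t,a)$ — smoking uptake, $M \to S$;
* $\delta(t,a)$ — cessation, $S \to E$ (ex-smokers never relapse;
  people who repeatedly quit and restart are treated as smokers
  throughout);
* $\lambda(t,a)$ — lung cancer incidence among never-smokers, elevated
  multiplicatively to $k_S\lambda$ for smokers and $k_E\lambda$ for
  ex-smokers;
* $\mu(t,a)$ — mortality from causes other than lung cancer, elevated to
  $(1+q_S)\mu$ and $(1+q_E)\mu$ for smokers and ex-smokers;
* $\nu(t,a)$ — excess mortality of lung cancer patients, who die at rate
  $\mu + \nu$.

In transport form the dynamics read
$(\partial_t + \partial_a)M = -(\mu + \sigma + \lambda) M$, and similarly
for the other compartments, with incidence flux
$\lambda (M + k_S S + k_E E)$ feeding $L$. Both derivatives act along
birth cohorts: a cohort at age $a$ in year $t$ is at age $a+1$ in year
$t+1$. The boundary condition at the youngest age is a yearly inflow
$B(t)$ of never-smokers; the initial condition is the full age
distribution of the four compartments in the first modelled year.

The four ratios $k_S, k_E, q_S, q_E$ are deliberately not estimated: they
are epidemiological quantities measured far more precisely in cohort
studies than a fitting exercise on surveillance counts could manage.
`default_hazard_ratios()` carries literature values for Japanese men
($k_S = 4.94$, $k_E = 2.20$, $q_S = 0.49$, $q_E = 0.20$) and women
($k_S = 4.25$, $k_E = 2.19$, $q_S = 0.51$, $q_E = 0.46$). Because $k_S$
is the most influential and most uncertain of the four,
`sensitivity_ks()` sweeps it over a grid of multipliers (default
0.5–1.5) without refitting anything else.

## Discretization: exact steps along characteristics

The yearly grid is aligned with the characteristics ($\Delta t = \Delta a
= 1$), so advancing the population is a sequence of independent
within-cell problems. Within one (year, age) cell the five rates are
frozen, making the four-compartment system a linear constant-coefficient
ODE. `advance_cell()` solves it exactly with a matrix exponential, on a
7-dimensional augmented generator whose three extra absorbing coordinates
accumulate other-cause deaths, lung cancer deaths and incident cases
during the step. Two properties motivated this over explicit
time-stepping:

* it is **exact** for piecewise-constant rates, so the only
  discretization decision is the (data-imposed) yearly resolution of the
  rate surfaces themselves;
* the step is a probability-preserving linear map, so compartments remain
  nonnegative and persons are conserved (entrants = survivors + deaths)
  to machine precision, whatever the rate magnitudes.

The test suite checks the step against an independently coded
Runge–Kutta integration (relative agreement $10^{-8}$ or better) and
against a $10^6$-agent event-driven stochastic microsimulation (agreement
within 3 Monte-Carlo standard errors), and checks the conservation
identity every simulated year at relative tolerance $10^{-10}$.

Ages are modelled from `a0` (default 0) to a closed top bin at `a_max`
(default 100, where census tables stop): cohorts reaching the top bin
remain there and keep experiencing the oldest cell's rates. The cell step
is implemented in C++ (RcppArmadillo); a full 101-age, 50-year simulation
costs roughly 20 ms, which is what makes likelihood maximization and
bootstrapping practical.

## Rate parameterization

`block_structure()` carves each surface into closed–open age and calendar
blocks and assigns one free parameter per block, stored as a log rate so
unconstrained optimization keeps rates positive. Default blocks follow
the strata of the data: 5-year age blocks for $\lambda$, $\mu$, $\nu$
(registry and vital-statistics resolution), 10-year blocks from age 20
for $\sigma$ and $\delta$ (survey resolution), and one block per calendar
year. Multi-year time blocks are a configuration choice used to keep
small synthetic fits cheap. Ages outside a symbol's block coverage are
structurally zero — that is how childhood smoking uptake is switched off
— and an empty edge vector removes a symbol from estimation entirely.

Beyond the last fitted year every surface is extended by carry-forward:
each forecast cell takes the value of the same age cell in the most
recent fitted year, preserving the final age profile verbatim
(`extend_forecast()`, idempotent by construction). This is deliberately
conservative: no trend extrapolation is invented beyond what the final
fitted year supports, and the forecast inherits exactly the most recently
observed schedule of uptake, cessation and hazards.

## Observation model and likelihood

Five stratified tables inform the fit: lung cancer incidence counts,
lung cancer death counts, other-cause death counts (5-year age groups ×
year), population counts (single year of age × year) and surveyed
current-smoker prevalence (10-year age groups × year). Counts are
modelled as independent Poisson draws around the model's expected
stratum totals; prevalence as binomial sampling of the model proportion
$S / (M + S + E + L)$ with the surveyed denominator. The prevalence
denominator includes $L$ because survey respondents are drawn from the
general population, of which diagnosed patients are a negligible
fraction. Surveys rarely publish their effective sample size, so the
binomial $n$ is an explicit input (synthetic default: 1000 per stratum).

All terms use exact log probability masses, written to accept
real-valued "counts" so that noiseless synthetic data (expectations in
place of draws) can be fitted in oracle tests; a zero model mean facing a
positive count contributes $-\infty$ rather than raising an error. A
year's flows are the events of $[t, t+1)$, so on a fitting grid ending
in year $T$ the flow tables extend to $T-1$ and the January-1 state
tables (population, prevalence) to $T$.

Two model inputs are taken from data rather than estimated: the boundary
inflow (population counts at the youngest modelled age, or the official
projection over the forecast horizon) and the initial compartment split
at the first fitted year. Real-data users must supply that initial state
(e.g. from a burn-in reconstruction); the synthetic generator returns its
ground-truth initial state alongside the observations.

## Estimation

`fit_mle()` maximizes the composite log-likelihood with L-BFGS-B on the
log-rate scale, under box bounds (defaults $[-16, 5]$, i.e. hazards
between $\sim 10^{-7}$ and $\sim 150$ per person-year). The lower bound
matters more than it looks: on the log scale the gradient with respect to
$\log r$ vanishes as $r \to 0$, so an unbounded quasi-Newton search that
overshoots a weakly identified rate toward zero lands on a flat shelf it
cannot leave. Bounding the rates away from that degenerate boundary made
every replicate fit in our experiments reach the same optimum as fits
started at the generating truth.

Starting values are crude data-derived rates (stratum events over person
years for $\lambda$ and $\mu$; prevalence-scaled uptake for $\sigma$;
constants for $\delta$, $\nu$), clamped into the box. Before optimizing,
every estimated block is checked for identifiability — each block must
overlap at least one stratum of the dataset that informs its symbol, with
uptake and cessation blocks allowed to be informed by surveys at the same
or older ages in the same or later years (the cohort carries the signal
forward along its characteristic). Unidentifiable blocks are reported by
name rather than silently producing a singular fit. The check is
necessary but not sufficient: near-collinear designs (for example a
single prevalence age stratum, which nearly confounds uptake with
cessation) still fit, but show up as near-zero Hessian eigenvalues and
trigger the repair warning below.

The covariance of the estimate is the inverse of a finite-difference
Hessian of the negative log-likelihood at the optimum. The Hessian step
(default $5\times10^{-3}$ on the log scale) is larger than the
optimizer's because second differences of a log-likelihood of magnitude
$10^5$–$10^6$ sit close to double-precision roundoff at smaller steps.
If the inverse is not positive semidefinite, negative eigenvalues are
clipped at a small floor and the result flagged (`psd_repaired`) with a
warning suggesting coarser blocks — finite-difference Hessians of
saturated models are fragile, and the flag is a signal to simplify the
block structure rather than to trust the repaired directions.

## Parametric bootstrap

`parametric_bootstrap()` draws replicate parameter vectors from a
multivariate normal centred at the estimate with the inverse-Hessian
covariance, evaluates any output functional per draw, and reports
elementwise percentile bands (2.5th/97.5th at the default level; the
reference analysis uses 1000 replicates). Drawing on the log-rate scale
— the scale on which the likelihood was maximized and is closest to
quadratic — was a deliberate choice; it also guarantees positive rates
in every replicate. Peak-burden intervals use per-replicate maxima: each
replicate trajectory contributes its own maximum (and its own argmax
year), and the interval is the percentile range of those maxima. This
direct bootstrap of the functional is wider than reading the envelope of
pointwise bands at the peak year and reflects the uncertainty of the
peak itself. Note the bands quantify parameter uncertainty only; they do
not widen for structural misspecification (see Limitations).

## Forecasting and summaries

`project_burden()` re-simulates from the first fitted year through the
horizon with carry-forward rates, switching the boundary inflow to the
exogenous projected-population table after the last fitted year.
Historical years therefore reproduce the fitted expectations exactly.
Results are summarized per year × age group (defaults 15–64, 65–74, 75+,
plus all ages): expected cases and deaths, rates per 100,000 using the
model population of the same stratum as denominator, current- and
ex-smoker prevalence, and population. `find_peak()` locates series
maxima (ties to the earliest year, flat and boundary series flagged).
`sensitivity_ks()` repeats the projection with $k_S$ multiplied,
everything else fixed, because the question it answers is how the
*prediction* responds to the assumed hazard ratio, not how the fit would
reabsorb it.

## The synthetic generator

`generate_observations()` turns a scenario — grid, per-sex rate surfaces,
hazard ratios, birth series, survey sample size, seed — into the five
observed tables plus projection, together with the noiseless truth. The
initial age profile is built by marching each pre-`t0` birth cohort
(sized by the birth series) through the first year's rate column, with
the over-`a_max` pool closed in closed form (a geometric sum of the
top-cell transition matrix), so constant conditions start exactly at
their stationary profile. The projected-population table over the
horizon is the model's own noiseless future population, which keeps the
forecast boundary condition consistent with the ground truth.

`japan_like_scenario()` provides the documented default world: male
uptake peaking near age 22, very high in the 1960s (adult prevalence
above 0.7) and declining steeply with calendar time; much lower female
uptake with a milder decline; cessation rising with age and over time;
Gompertz-like background mortality with slow secular improvement; a
never-smoker cancer hazard rising steeply after age 40 with a calendar
trend; an excess case fatality near 0.25–0.28 per year (roughly a 30%
five-year survival); and a birth series with a 1949-style baby boom, a
1973 echo and a long fertility decline. Population scale (births in the
tens of thousands rather than millions) is chosen so that a full fit runs
in minutes; all rates, proportions and peak timing are scale-free. Under
these defaults absolute male cases peak in the late 2030s and decline
afterwards while all-ages rates per 100,000 keep rising — the signature
pattern of a shrinking, ageing population with falling smoking
prevalence.

What the generator does *not* emulate: smoking dose (pack-years) and
duration structure, secondhand exposure, registry under-ascertainment or
coverage changes, survey design effects beyond an effective binomial
sample size, migration, and cohort effects in the hazards beyond what the
(year, age) surfaces express. Passing tests on synthetic data therefore
demonstrate that the pipeline recovers what it models — not that the
model captures everything in real registry data.

`blockwise_scenario()` is the testing workhorse: truth surfaces exactly
block-constant on a given structure, so maximum-likelihood recovery can
be asserted block by block (noiseless recovery to well under 1% in the
acceptance suite) and bootstrap interval coverage can be measured over
replicate datasets (between 90% and 99% empirically at the 95% level).

## Numerical choices and problem sizes

* Matrix exponentials use Padé scaling-and-squaring (Armadillo
  `expmat`); numerical failures at absurd rates during a line search are
  mapped to a large penalty rather than aborting.
* Conservation is asserted at $10^{-10}$ relative; the step-vs-RK4
  comparison at $10^{-8}$; closed-form cohort survival at $10^{-8}$.
* Tiny negative compartment values from roundoff are floored at zero
  after each step.
* Degenerate inputs: all-zero rates are legal (pure aging); an all-equal
  burden series reports its earliest year with a `flat` flag; a maximum
  at the final year carries a `boundary` flag.
* The acceptance script fits both sexes on a 1990–2014 window at ages
  0–100 with survey-style age blocks and two calendar blocks for uptake
  and cancer hazards (about 30 parameters per sex), then bootstraps the
  2065 forecast with 200 replicates; test-suite fits use 10-year,
  20–25-age grids with 5–7 parameters. These sizes are the package's
  default desk-scale study conditions; the machinery itself is
  indifferent to the grid.

## Limitations

* Carry-forward rates make the forecast a "most recent schedule
  continued" statement, not a trend extrapolation; calendar trends that
  continue past the fitting window (e.g. further cessation growth) are
  not anticipated.
* Bootstrap bands cover sampling uncertainty of the estimated rates
  only. When coarse blocks approximate smoothly varying truth, the bands
  can be far narrower than the actual error of the projection — visible
  in our synthetic experiments, where a two-block-in-time fit places the
  male case peak a few years early with a narrow interval.
* The composite likelihood treats the five tables as independent;
  registry and vital-statistics counts derived from overlapping
  populations may be mildly correlated in reality.
* No screening, treatment-improvement or intervention scenarios; no
  cure or remission from the cancer compartment; mortality inside the
  cancer compartment uses baseline $\mu$ plus excess $\nu$ without
  smoking elevation, and diagnosed patients no longer change smoking
  state.
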