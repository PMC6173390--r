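---
title: "Modeling body-weight impacts of added-sugar reformulation in beverages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling body-weight impacts of added-sugar reformulation in beverages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbreform)
```

`ssbreform` simulates a national policy that gradually reduces the added
sugar content of sugar-sweetened beverages (SSBs), and propagates the
resulting caloric change through an individual-level dynamic
energy-balance model to survey-weighted changes in body weight, BMI and
obesity prevalence. This vignette is the package's own account of the
science: the model and its assumptions, the parameters that matter, the
numerical choices, and what the synthetic-data machinery does and does
not establish.

## The policy question and its algebra

Dietary guidelines recommend keeping added sugars below 10% of total
energy intake (TEI). Given a survey sample of adults with 24-h recall
intakes, the package first asks, person by person, how much SSB added
sugar would be compatible with that goal if the removed sugar also
reduced total energy one-for-one. Writing `tei` for baseline energy,
`ssb` for baseline SSB added sugar and `oth` for added sugar from other
sources, the post-reformulation share condition

```
goal = (ssb_max + oth) / (tei + (ssb_max - ssb))
```

has the closed-form solution implemented in `max_ssb_sugar()`:

```
ssb_max = (goal * (tei - ssb) - oth) / (1 - goal).
```

Three regimes follow (`delta_change()`): no change when current SSB
sugar is already at or below the maximum; a reduction down to exactly
the maximum otherwise; and full removal of SSB sugar when non-SSB
sources alone exceed the goal (`ssb_max < 0`). The printed statement of
the middle rule in the source material uses the same inequality twice;
the only reading consistent with the balance equation — reduce when the
initial intake *exceeds* the maximum — is the one implemented, and
`test-reformulation-target.R` verifies by back-substitution that
middle-rule individuals land on exactly 10% of energy.

The population-level requirement is the survey-weighted mean of the
individual reduction proportions `prop_i = |delta_i| / ssb_i`
(`required_proportion()`). For non-consumers the ratio is undefined; we
define `prop = 0`, the continuous extension of a zero change, and expose
a consumers-only denominator as an alternative because the aggregation
convention is genuinely ambiguous. The raw requirement is rounded down
to a 5% policy grid (`round_target()`), e.g. 52.2% becomes 50%.

## Rollout schedules

A reformulation target is phased in over `k` years (default 10). Three
shapes are provided (`reduction_schedule()`):

* **decreasing**: a constant multiplicative step. The first-year
  reduction solves `1 - (1 - target)^(1/k)`; cumulative reductions are
  `1 - (1 - r1)^j`. For a 50% target over 10 years: 6.7%, 12.9%, 18.8%,
  ..., 50%.
* **constant**: linear, `target * j / k` (5 points of baseline content
  per year in the main scenario).
* **increasing**: the decreasing scenario's yearly increments in reverse
  order (3.6% in year 1, the largest step last). We define this scenario
  *operationally* by increment reversal rather than by a closed-form
  exponent: the reversal is unambiguous, reproduces both published
  endpoints, and makes the reversal property testable to 1e-12.

Schedules are step functions: the year-`j` cumulative fraction applies
from the start of policy year `j` (day `365*(j-1)+1`), matching annual
regulatory updates. Whether the published analysis stepped annually or
interpolated continuously is not stated; annual steps are used because
the three shapes converge at the reporting horizon either way (verified
to < 0.02 kg in the acceptance suite).

## Compensation and the energy-change trajectory

People partially compensate for removed calories. With compensation `c`
(percent), the net daily change when the cumulative reduction is `r` is

```
delta_intake = -ssb * r * (1 - c/100)
```

(`caloric_change()`). The main scenario uses `c = 43`; a 50 kcal/day
gross cut then nets 28.5 kcal/day. `build_trajectory()` expands this
into a daily series over the simulation horizon (default 12 years: 10
years of rollout plus 2 years at the final content, long enough for the
lagged weight response to be near its plateau while the three rollout
shapes agree).

**Carbohydrate accounting.** The weight model's glycogen and fluid
compartments respond to *carbohydrate* intake. Removed SSB sugar is
carbohydrate, but the compensating calories come from unspecified mixed
sources, so the carbohydrate content of the *net* change is a modeling
choice. The package default (`carb_accounting = "net"`) forces the
glycogen/fluid channel with the net energy change (times
`carb_fraction`, default 1). This is the convention of the reference
implementations of the adult model, and it preserves an exact boundary
condition that anchors the whole sensitivity analysis: at 100%
compensation the intervention is a strict null — every compartment
derivative is identically zero and the simulated weight change is
exactly 0 kg, not merely small. The alternative (`"gross"`), in which
compensated calories are assumed entirely non-carbohydrate so glycogen
tracks the full sugar cut, is available as a configuration switch; it
shifts 12-year weight changes by under 0.1 kg but breaks the
full-compensation null by a few tens of grams of glycogen-bound water.

## The dynamic weight model

Each adult is represented by fat mass `F`, lean tissue `L`, glycogen `G`
(carrying `hydration_ratio` = 3.7 g water per g), extracellular fluid
`ECF`, and an adaptive-thermogenesis offset `AT`. Body weight is
`F + L + G*(1+3.7) + ECF`. Total expenditure is

```
TEE = k + gamma_f*F + gamma_l*L + delta*BW + beta_tef*dEI + AT + (synthesis costs)
```

with tissue coefficients `gamma_f = 3.2`, `gamma_l = 22` kcal/kg/day, a
thermic effect `beta_tef = 0.1` of the intake change, and
first-order adaptive thermogenesis relaxing toward `beta_at * dEI`
(`beta_at = 0.14`, `tau_at = 14` days). The physical-activity term
`delta * BW` is essential to the model's responsiveness: without it the
marginal expenditure per kilogram is only ~4.6 kcal/kg/day and a 29
kcal/day deficit would imply an implausible 5+ kg loss. `delta` is
derived per individual from the physical activity level (`pal`, default
1.55) and a Mifflin-St Jeor resting metabolic rate, the convention of
the adult model family, and can be fixed globally via `delta_activity`.

Energy imbalances `EB = intake - TEE - rho_g*dG/dt` are partitioned by
the Forbes share `p = C/(C+F)` (`C = 10.4 * rho_l/rho_f` kg): `rho_f
dF/dt = (1-p) EB`, `rho_l dL/dt = p EB`, with energy densities
`rho_f = 9440`, `rho_l = 1816`, `rho_g = 4180` kcal/kg and synthesis
costs `eta_f = 180`, `eta_l = 230` kcal/kg folded into an implicit
linear solve for `TEE`. Glycogen relaxes toward
`G_b * sqrt(CI/CI_b)` where `CI` is carbohydrate intake (baseline share
`carb_share = 0.5` of energy) and extracellular fluid follows the
sodium/carbohydrate feedback with `xi_na = 3000`, `xi_ci = 4000`,
`[Na] = 3220`. Dietary sodium is untouched by a sugar reformulation, so
only the carbohydrate channel is active. All constants are arguments of
`model_params()`; none is hard-coded.

**Calibration.** Baseline fat mass comes from the ln(BMI) body-fat
regressions (per sex, with age), clamped to `fat_bounds` = 5-60% of
weight with a warning; lean tissue is the residual mass. Each individual
is then placed exactly in energy balance by solving
`k = tei - gamma_f*F0 - gamma_l*L0 - delta*W0` in closed form
(`calibrate_steady_state()`), so a zero-change simulation is a fixed
point to machine precision. Age is held at baseline over the simulation:
the scenario assumes steady state and no behavioral change apart from
the regulation, and aging physiology is outside its scope.

**Numerics.** The stacked cohort system (6 states per individual,
including a cumulative energy-imbalance audit state) is integrated with
`deSolve`'s fixed-step classical Runge-Kutta scheme at 1-day steps
(`step_days`), with output aligned to policy-year boundaries. The
fastest mode (glycogen, rate ~1/day) is comfortably inside the RK4
stability region at this step; halving the step moves 12-year weights by
under 1e-5 kg (tested). Degenerate inputs are handled explicitly:
targets 0 and 1 are admitted for sensitivity grids (all-zero and
all-one schedules); carbohydrate intake and glycogen are clamped at zero
when an extreme grid cell cuts more carbohydrate than the assumed
baseline; a zero-dispersion energy-ratio sample excludes nobody in the
plausibility filter.

The energy-conservation identity
`rho_f*dF + rho_l*dL + rho_g*dG = integral(intake - TEE)` holds by
construction at the derivative level and is re-checked after
integration. The long-run response is validated against an independent
oracle that never touches the ODE path: root-finding for the
post-intervention steady state along the Forbes curve
`L(F) = L0 + (rho_f/rho_l) * C * ln(F/F0)` with quasi-static glycogen,
fluid and thermogenesis limits, which agrees with a 40-year constant
-100 kcal/day simulation to ~1e-7 kg.

## Survey aggregation

Final weights become BMI and the categories `normal` (< 25, including
underweight), `overweight` (25 to < 30) and `obese` (>= 30), with
half-open boundaries. `weighted_summary()` produces weighted mean
changes and prevalences overall and by sex, age group (20-39, 40-59,
60+) and SES tertile; absolute prevalence changes in percentage points,
relative changes as percent of baseline prevalence, and projected case
counts against an externally supplied adult population (each stratum
receives its share of the survey weight mass; the 90 million default is
a documented example value, never fetched).

Design-based uncertainty is computed two ways, because the published
convention for this kind of analysis is a survey package whose internal
method is not part of the result: a Rao-Wu-Yue rescaling bootstrap over
PSUs within design strata (default, 500 seeded replicates; all derived
quantities recomputed per replicate), or Taylor linearization with the
with-replacement PSU approximation and t quantiles at the design degrees
of freedom (PSUs minus strata). Under linearization, intervals for
relative changes and case counts are rescaled from the
percentage-point interval with the baseline prevalence treated as
fixed. Model-parameter uncertainty is deliberately not propagated: the
weight model is deterministic, so intervals reflect sampling design
only.

## The synthetic population

`generate_population()` exists so that every stage is testable without
any external download. It emulates the *statistical shape* of a national
adult dietary survey: ~3,005 records expanding to ~64.9 M adults; mean
added sugar 244.9 kcal/day (12.6% of energy) with 101.1 kcal/day from
SSBs; 51.8% SSB consumers in the past 24 h (zero-inflation of a 24-h
recall); log-normal energy and sugar-share distributions
(`sdlog` 0.30 and 0.50 — right-skewed, positive dietary data); sex, age
and SES intake gradients composed multiplicatively from marginal means,
each factor normalized so the configured overall means are reproduced in
expectation; per-sex log-normal BMI solved to match category prevalences
near 30.4/38.7/30.9%; a weak diet-BMI Gaussian-copula correlation
(0.1); 30 design strata x 3 PSUs with a 0.02 intraclass correlation of
log intake so design-based variance is exercised; and log-normal survey
weights (CV 0.3) rescaled to the target expansion.

What it does **not** emulate: the real sampling frame and nonresponse
adjustment, food-item-level recall structure, day-to-day intake
variation, seasonality, recall underreporting correlated with BMI, or
the joint sex-age-SES BMI gradients (BMI is calibrated per sex only;
the overall prevalence split follows from the sex mixture). Passing
tests therefore establish that the pipeline's arithmetic, dynamics and
estimators are correct — not that any particular national estimate is
reproduced. The distribution of individual reduction proportions, in
particular, depends on the joint intake structure, so the synthetic
requirement (~14%) differs from an analysis of the real survey; the
package applies whatever policy target it is given.

The exclusion filters mirror the analytic-sample rules: energy reporters
beyond 3 SD of the sample's `ln(TEI/TER)`, SSB intake above 3,000
kcal/day, age under 20, missing anthropometry. The total energy
requirement (TER) model behind the first rule is switchable
(`"expenditure"`: the weight model's baseline expenditure at default
activity, the self-consistent default; `"mifflin"`: RMR x PAL) because
the original TER equations are external; conveniently, the centered
3-SD rule is invariant to any multiplicative rescaling of TER, so the
choice barely moves the kept set. The rule set is applied in a single
pass on the input sample, as in the emulated analysis.

## Problem sizes and runtime choices

The test suite runs cohorts of 25-300 individuals over 2-12 simulated
years and one calibration population of 3,000, sizes chosen so the full
suite completes in about a minute while every property is exercised at
realistic scale; the acceptance script runs the full default population
(~3,000 records) over the complete 12-year horizon. The 5x5
sensitivity grid in the acceptance suite uses 150 individuals per cell,
which bounds grid runtime at roughly half a minute without changing any
monotonicity conclusion (the grid properties are exact inequalities, not
sample-size-dependent estimates).

## Known limitations

* The compensation fraction is a single population-wide constant; no
  heterogeneity or beverage-specific substitution is modeled.
* The weight model is adult-only; growth energetics for children and
  adolescents are out of scope.
* Confidence intervals reflect survey design only, not weight-model
  parameter uncertainty.
* The glycogen/fluid sub-model is quasi-empirical; it can be disabled
  (`fluid_compartments = FALSE`) to isolate the validated fat/lean
  core.
* Annual-step rollouts and a fixed 365-day year are conventions; both
  wash out at the 12-year reporting horizon.
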