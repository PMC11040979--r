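---
title: "Methods: a discrete-event microsimulation of type 2 diabetes burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a discrete-event microsimulation of type 2 diabetes burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`t2dsim` simulates a national population one individual at a time, in
annual cycles, through three health states: healthy, type 2 diabetes
(T2D, absorbing) and death. Per cycle and alive individual the engine
(i) increments age, (ii) updates the modifiable risk factors by
net-transition draws, (iii) draws T2D onset from the FINDRISC-derived
annual probability (healthy adults at or above the age floor only), and
(iv) draws survival from state-appropriate mortality. Onset and death
may occur in the same year; the dead are never revisited; demographics
other than age never change.

Key structural assumptions:

- **Independent individuals.** No household linkage: every person is an
  independent unit (household size of one).
- **Open cohort.** A constant annual birth cohort (default: the baseline
  age-0 count) enters with lowest-risk factor states; migration is not
  modelled, which in real applications understates burden.
- **Fixed prevalence curves.** Risk-factor prevalence-by-age curves are
  held constant over calendar time; transitions encode ageing along the
  curve, not secular trends.
- **Minors.** Below 18, waist, blood-pressure medication, glucose
  history and T2D are held at the lowest-risk state (surveys do not
  measure them in children); BMI class does evolve. Risk becomes fully
  dynamic on ageing into adulthood, and T2D incidence starts at 35.

## Synthetic population

The baseline population is expanded from a survey-like sample by
weighted sampling with replacement within age group × sex × province
strata until the stratum target count is met *exactly* (a hard
invariant, not a stochastic one). Education, income and risk factors
ride along with the sampled donor, so the survey's correlation
structure is preserved; the donor's exact age is retained, group totals
applying at group level.

The survey fixture itself is generated, not shipped: for each age group
the joint distribution of the categorical variables is the product of
the configured marginals, tilted by adjacent-category odds multipliers
(`odds^((i-1)(j-1))` for ordered category indices *i, j*) and then
projected back onto the marginals by iterative proportional fitting
(IPF). IPF preserves the tilt's local odds ratios while matching each
marginal exactly in expectation, so associations and marginals can be
configured independently. The default multipliers (BMI–waist 3.0,
education–BMI 0.6, BMI–medication 1.6, BMI–glucose 1.5, glucose–T2D
4.0, medication–T2D 1.5) encode the monotone associations one expects
in health-interview data; they are a stated world, not estimates.

What the generator does **not** emulate: measurement error and
self-report bias, item non-response (the fixture is complete by
construction — multiple imputation of a real survey is out of scope),
household clustering, and any within-age-group age gradient of the risk
factors. A green calibration test therefore establishes that the
expansion machinery reproduces its targets, not that the targets match
any particular real population.

The bundled baseline marginal table reports region, not province;
province targets split each region's share uniformly across its
provinces (1 + 5 + 5). A real application should supply province
marginals via `read_marginals()`.

## Net annual transition probabilities

Two consecutive cross-sections cannot identify a full bidirectional
transition matrix, so flows between adjacent ordered states are *net*:
per state boundary, at most one direction is nonzero, the direction
fixed by the sign of the cumulative-prevalence change the flow must
produce. Calibration minimises ‖p(a+1) − p(a)·Q‖² by Nelder–Mead
simplex (max 2000 iterations, relative tolerance 1e-14) with flows
logit-transformed to stay in (0, 1) and a quadratic penalty on negative
diagonals; the closed-form boundary-crossing solution
(flow = |ΔF|/p_source, clipped) seeds the optimiser and serves as the
independent oracle in the tests. An achieved objective above 1e-10
flags the row as infeasible best-fit (e.g. a required flow out of an
empty state). Prevalence curves are smoothed first by a centred moving
average (default window 5 years, truncated at the boundaries,
renormalised jointly across states); calibrating age *a* → *a+1* from a
period curve is a period-as-cohort approximation, accepted and
documented. Identical (p_from, p_to) pairs are calibrated once and
reused, which is what makes the default tables (curves replicated
across sex × region × education) cheap.

## Incidence and mortality

The concise FINDRISC logistic model supplies the 10-year risk from age
band, BMI class, sex-specific waist class, blood-pressure medication
and glucose history; the published point estimates are bundled, and the
top age-band coefficient is carried forward above 64 (an extrapolation
— the model was estimated on 35–64-year-olds). The 10-year risk
converts to a one-year probability under a constant hazard,
p₁ = 1 − (1 − p₁₀)^(1/10); the naive p₁₀/10 alternative was rejected
because it breaks the probability scale at high risk and fails the
round-trip identity the tests enforce. Incidence is simulated from age
35 (the risk equation's validated range); the annual probability is 0
below the floor.

Mortality rates convert to probabilities by 1 − e^(−r) (constant hazard
within the year). Healthy individuals face the cause-deleted rate
(all-cause − T2D-cause); individuals with T2D face RR(age, sex) ×
all-cause, capped so the annual probability stays ≤ 0.999. How a T2D
individual's death is attributed to T2D is not specified by mortality
statistics alone; the package attributes probabilistically by the
excess fraction (RR·r_ac − (r_ac − r_t2d))/(RR·r_ac), clipped to
[0, 1] — the natural choice that makes attributed deaths vanish exactly
when RR = 1 and r_t2d = 0. Ages beyond the last table row reuse that
row (open interval). The bundled mortality table is a synthetic
Gompertz–Makeham (2e-4 + 2e-5·e^(0.095·age), sex multipliers 1.30/0.78,
region multipliers 1.02/0.93/1.12) and the bundled relative risks are
synthetic values with the canonical shape (declining with age, higher
in women, all ≥ 1); both are replaceable via CSV and are labelled
synthetic because the source extracts are not redistributable.

## Burden accounting

Rates are per 100,000 with mid-year denominators (end-of-year alive
plus half the year's deaths) restricted to ages 35–80; individuals may
age past 80 and remain simulated but leave the reporting window.
YLL(y) sums remaining life expectancy at the age of each T2D-attributed
death; YLD(y) is prevalent person-years (trapezoid of consecutive
end-of-year counts) times the disability weight; DALY = YLL + YLD
exactly, asserted on every output row. The first simulated year has no
person-year interval and reports NA. Defaults: disability weight 0.049
(uncomplicated-diabetes convention; 0 is allowed for pure-YLL
accounting) and a reference life table derived by closure from the
package's own mortality table — both configurable, and no acceptance
result depends on their specific values.

## Inequality and validation metrics

Groups ordered along the social spectrum are placed at ridit scores
(midpoints of cumulative population share). SII is the slope of a
share-weighted linear regression of the rate on the ridit; RII is the
ratio of predicted rates at ridit 1 vs 0 from a share-weighted
log-linear fit (a weighted quasi-Poisson variant is available behind a
flag, since the exact link is a free choice). Zero rates are floored at
a configurable epsilon and flagged before the log fit. Confidence
intervals use a parametric bootstrap on group case counts given
denominators (200 resamples by default) — equivalent, at the
aggregation level the metric consumes, to resampling individuals, and
much cheaper. Validation uses the two-way random-effects
absolute-agreement single-measure ICC with its F-based confidence
interval, computed from the ANOVA mean squares.

## Uncertainty

The probabilistic sensitivity analysis performs (by default) 100 runs
on a 1% subsample, stratified by age group × sex × region so the
population structure survives subsampling. Per run, FINDRISC
coefficients are drawn Normal(point, SE) and relative risks lognormal
from their 95% CI; mortality rates and transition probabilities are
held fixed by default (their sampling uncertainty is comparatively
small), flag-enabled otherwise. The 95% uncertainty interval is the
2.5th–97.5th percentile across runs; the point estimate comes from an
all-parameters-at-point run on the *full* population and is therefore
not guaranteed to lie inside the subsample-based interval. Runs share
the master simulation seed (common random numbers): run-to-run spread
reflects parameter draws and subsampling only, which makes the interval
collapse exactly when all parameter distributions are degenerate and
the sample fraction is 1 — a property the acceptance tests assert. The
subsample is redrawn each run by default (configurable to a fixed
subsample). The bundled FINDRISC standard errors are synthetic
plausible values, as flagged in the parameter file.

## Numerical choices

- Probability-vector and share sums are validated to 1e-9; IPF iterates
  to a 1e-12 margin deviation (cap 2000 sweeps).
- Calibration declares an exact solution at objective ≤ 1e-10; tiny
  negative diagonals (> −1e-9) from floating point are clamped and rows
  renormalised.
- Degenerate inputs: degenerate marginals (probability 1 on one
  category) produce identical individuals; equal prevalence
  cross-sections produce the identity matrix without invoking the
  optimiser; an empty donor stratum or missing table stratum fails
  before any mutation, naming the stratum.
- One seeded RNG stream per run; per-individual draws are consumed in
  id order, so identical seeds give byte-identical event logs. Derived
  seeds stay below 2³¹.
- Configs are JSON (the R environment ships no YAML parser);
  `validate_config()` reports field paths before any computation.

## Limitations

Everything quantitative about the bundled defaults — prevalence curves
anchored only at age-group level, synthetic mortality/RR tables,
synthetic FINDRISC SEs, uniform province splits — is a stand-in world:
the package's forecasts under these defaults are internally coherent
but are not forecasts for any real country. Secular risk-factor trends,
migration, intervention scenarios, cause-of-death detail beyond the
T2D/other split, DALY discounting and age-standardisation are out of
scope by design.
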