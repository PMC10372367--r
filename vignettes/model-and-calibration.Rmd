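---
title: "The myopia cost-effectiveness model: structure, calibration and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The myopia cost-effectiveness model: structure, calibration and uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myopiaCEA)
```

## The decision problem

School-age myopia in China is managed through three competing strategies
that share a school-based vision-test cascade and differ in how (and whether)
health education reaches students and parents:

* **School-based screening** — non-cycloplegic vision tests every school
  term (collapsed here to one effective annual screening event with coverage
  91.8%), referral of screen-positives to hospital for cycloplegic
  confirmation, and correction for those who comply. No health-education
  channel.
* **Traditional prevention and control** — screening plus conventional
  health education (posters, brochures, thematic activities) promoting
  outdoor activity and follow-through on referral and correction.
* **Digital comprehensive prevention and control** — the same content
  delivered through WeChat/SMS, with the higher compliance levels observed
  for digital channels.

`myopiaCEA` reproduces the full decision-analytic pipeline around this
comparison: a Markov cohort model of myopia progression, discounted
societal costing, QALY/DALY accrual, incremental cost-utility (ICUR) and
cost-effectiveness (ICER) analysis against WHO GDP-multiple thresholds,
one-way and probabilistic sensitivity analysis, and perfect-compliance
subgroup scenarios — separately for rural and urban settings.

## Markov cohort engine

The cohort enters at age 6 and is followed to age 18: 13 annual age points,
12 transitions. Four health states are defined on cycloplegic spherical
equivalent (SE): non-myopia (SE > −0.5 D), low (−3.00 < SE ≤ −0.50),
moderate (−6.00 < SE ≤ −3.00) and high myopia (SE ≤ −6.00). Payoffs accrue
at every age point, discounted by $(1+r)^{-(a-6)}$.

Two modelling conventions are worth making explicit:

* **Irreversibility.** No transition moves toward a less myopic state, and
  within one annual cycle a child advances at most one severity level
  (onset enters at low myopia). Refractive error in children essentially
  never regresses, and the published prevalence trajectories are monotone;
  this convention also guarantees monotone total and high-myopia prevalence,
  which the test suite asserts as an invariant.
* **Intervention arithmetic.** A strategy modifies a natural-history
  transition probability $p$ to $p\,(1 - \mathrm{reach}\times(1 - m))$,
  where $m \in (0,1]$ is the effect multiplier among children actually
  reached. For treatment effects the reach is the product of the cascade
  stages, $\mathrm{coverage}\times\mathrm{sensitivity}\times
  \mathrm{referral}\times\mathrm{uptake}$; for education-delivered outdoor
  activity it is $\mathrm{exposure}\times\mathrm{compliance}$, independent
  of the screening result because education targets all students. The
  multiplicative composition is this package's construction — the source
  analysis names the cascade stages but not their composition rule — and it
  is the natural choice when stage compliances are conditionally
  independent.

False-positive screenees (non-myopic children failing specificity) incur
one confirmatory-examination cost but no health effect, consistent with a
societal costing perspective.

## Economic layer

Costs are in 2021 USD (6.45 CNY/USD; older cost data brought forward at 5%
per year). Per-cycle expected costs combine per-student program lines
(health education, school screening) with event costs along the cascade
(hospital examination, treatment), each split into direct-hospital,
direct-outside (transport, food, accommodation) and indirect (family
working-time loss) components. QALYs weight occupancy by per-state
utilities; DALYs use per-state disability weights in a prevalence-based
years-lived-with-disability accrual — the model has no mortality, so there
is no years-of-life-lost term.

The outcome discount rate is not stated in the source text. The package
defaults to 5%/year — matching the stated cost-adjustment rate, and the
only rate consistent with the printed cumulative QALYs (≈ 9.58 per person;
13 undiscounted person-years would be 13.0, and the 5%-discounted maximum
is 9.8633). It is configurable, including 0, and every report prints the
rate used. Half-cycle correction is off by default (the source is silent)
but available as a config option.

WHO thresholds classify a ratio against 1× and 3× per-capita GDP
($10,167 rural, $13,856 urban, giving $30,501 and $41,568 as the 3×
thresholds). The derivation of the two setting-level GDPs from the national
constants (GDP $12,551, urbanization 0.65, income ratio 2.5) is not
reproducible from the printed constants alone (they satisfy the
population-weighted mean but not the stated ratio), so both figures are
treated as direct inputs.

## Incremental analysis

`incremental_analysis()` sorts strategies by cost, flags strict dominance,
then applies extended dominance iteratively (a strategy whose incremental
ratio against the previous survivor exceeds the next survivor's is removed
from the frontier). Dominated strategies remain in the table with their —
possibly negative — ratios for transparency. Ratios are kept at full
precision internally and rounded to whole dollars only for display.

The published base-case table instead compares every strategy to the
previous *row* regardless of dominance; `sequential_increments()`
reproduces that presentation convention, and `make_scenario_bundle()` uses
it for the table-shaped outputs. Dominance is evaluated on both the QALY
and the DALY scale; when the two orderings disagree (they do in the urban
setting, where the traditional strategy's sequential ICURs decrease) the
package reports both and warns.

## The surrogate parameter set

The original appendix with age-specific transition probabilities, test
characteristics, effect sizes, utilities, disability weights and unit
costs is not publicly available. The calibration module
(`calibrate()`) therefore fits a complete stand-in parameter set to the
published outputs:

* age-6 baseline state occupancy (rural 4.83/0.07/0.09%, urban
  12.56/0.19/0.25% low/moderate/high — inputs, not fitted);
* age-18 total myopia prevalence for all six setting × strategy cells
  (89.16/87.63/85.37% rural, 90.04/88.64/86.56% urban);
* the reduction in age-18 high-myopia prevalence under the digital
  strategy (1.81 pp rural, 1.35 pp urban);
* per-person discounted cost, QALY and DALY for all six cells, and the
  perfect-outdoor-compliance variant costs ($321 rural, $808 urban), with
  the remaining subgroup-variant costs as soft targets.

The fit is deterministic and staged. Because NON_MYOPIA occupancy decays as
$\prod_a (1 - o(a))$, the onset scale is solved exactly by 1-D root finding
against the screening-strategy age-18 prevalence; the traditional and
digital per-cycle onset factors are solved the same way and then decomposed
into an outdoor-activity multiplier and education exposures (digital
exposure fixed at 0.90). A 6-parameter box-constrained search (progression
scales for the two within-myopia transitions; referral and spectacle
compliance of the screening-only and traditional strategies relative to the
digital anchors 0.353/0.36 rural and 0.733/0.683 urban) then minimises the
weighted squared relative error of the remaining targets. Inside each
evaluation, utilities and disability weights come from an order-constrained
linear fit (disutility increments parameterised on the log scale), and the
five unit-cost lines from non-negative least squares with heavily weighted
anchor rows.

Identifiability deserves honesty: roughly 20 printed targets cannot pin
down 12 free probabilities per transition per setting, so onset and
progression follow low-dimensional piecewise-linear age curves (knots at
ages 6/10/13–14/17, onset peaking near age 13 as in Chinese incidence
data), and weak priors select plausible points on the near-solution
manifold — utilities near 0.93–0.96 for corrected-range myopia, disability
weights of order 0.003–0.2 increasing with severity, screening test
sensitivity 0.90 and specificity 0.95 for non-cycloplegic testing. Several
parameter sets reproduce the anchors equally well; the fit report
(`calibration_report()`) states this degeneracy, and per-setting payoff
weights and unit costs are allowed to differ between rural and urban (the
printed DALY levels are nearly equal across settings despite very
different myopia burdens, which no shared weight set can reproduce).

Calibration is a build-time step: its output is committed as the packaged
fixture (`mpc_reference_params()`), so tests and analyses never depend on
optimizer behaviour. Every artifact derived from it carries the provenance
label `"calibrated surrogate, not original appendix values"`. The fit
report shipped alongside the fixture shows all hard targets within
tolerance (prevalences within 0.05 percentage points, cost/QALY/DALY
anchors within 1% relative).

Two published quantities are deliberately *not* hard targets. First,
printed ICURs/ICERs other than the rural traditional ICUR ($6,309 =
4,700,000/745) are not recoverable from the rounded printed inputs (e.g.
10,600,000/939 = 11,289, printed 11,301), so exact agreement is impossible
for any parameter set; the model's own full-precision ratios land in the
same classification bands. Second, the subgroup table's DALY pattern
implies mechanism differences between compliance levers (near-identical
proportional reach increases with very different printed effects) that a
multiplicative cascade cannot and should not chase.

### Subgroup scenarios: one-at-a-time, not cumulative

The subgroup analysis perfects one compliance field of the digital strategy
at a time (outdoor activity, vision-test coverage, spectacles, hospital
examination), comparing each variant to the previous row in that order.
The published table's levels identify this construction: under cumulative
perfection DALYs could only fall along the chain, yet the printed
perfect-coverage DALY (0.05878 rural) *exceeds* the perfect-outdoor value
(0.05766) while sitting below the digital base case (0.05905), and the
printed costs match one-at-a-time variants ($321 ≈ digital $324 minus the
referral/treatment savings from extra outdoor activity). A cumulative mode
remains available (`subgroup_scenarios(..., mode = "cumulative")`).

## Sensitivity analysis conventions

* **One-way:** parameters move to base × (1 ± f) with f = 10% for
  probabilities/weights and 20% for costs (the source states "10% or 20%"
  without a mapping); perturbed probabilities leaving [0, 1] are clipped
  with a logged warning. Tornado output orders parameters by ICUR range.
* **PSA:** 10,000 Monte-Carlo iterations by default; beta distributions
  for bounded quantities and gamma for costs, moment-matched so the mean
  equals the base value exactly. The source gives families but not
  dispersions; defaults are an effective sample size of 100 for beta and a
  coefficient of variation of 0.2 for gamma — conventional health-economics
  PSA practice — both configurable, with degenerate (variance-zero)
  settings reproducing the base case exactly. Parameters shared between
  strategies use a single draw per iteration, keeping strategies
  correlated. Severity ordering of sampled utilities/disability weights is
  enforced by sorting within each draw.
* **CEAC:** the probability a strategy is optimal is the fraction of
  iterations in which it maximises net monetary benefit
  (effect × willingness-to-pay − cost), evaluated on 101 evenly spaced
  willingness-to-pay points from 0 to 4× per-capita GDP. Probabilities sum
  to 1 at every grid point by construction.
* **Percentiles:** 2.5th/97.5th by linear interpolation between order
  statistics (quantile type 7), stated in all output metadata.

## What the generator emulates — and what it does not

`generate_initial_guess()` plus `calibrate()` play the role of the
unavailable appendix: they produce a parameter set under which the model
reproduces the published aggregate outputs under the published study
conditions (100,000-child cohorts, the printed compliance anchors, 2021
price level). The surrogate does not claim to recover the original
parameter values; age-resolved prevalence between ages 7 and 17 follows the
assumed smooth curves rather than observed data; costs are fitted bundles,
not ingredient-level prices; and the model inherits the source analysis's
own exclusions — no pathological-myopia complications or adult outcomes, no
other paediatric eye disease, no natural-environment covariates, no
individual-level heterogeneity beyond the four states. Passing tests
therefore demonstrate internal reproduction of the published surface, not
external validity of the surrogate parameters.

## Numerical choices and problem sizes

Occupancy conservation is enforced at 1e−9 and the cohort engine matches an
independent dense matrix-multiply oracle at 1e−12. Root finding uses
tolerance 1e−14 on prevalence products; ties in dominance sorting break by
effect, with equal-cost-equal-effect rows flagged as duplicates in stable
order. Degenerate inputs are defined rather than rejected where a
convention exists: cohort size 0 keeps per-person outputs, an empty effect
set is natural history, zero incremental effect yields a signed-infinity
ratio sentinel with a dominance flag.

The shipped analyses are small: a cohort run is 12 products of a 4-vector
with a 4×4 matrix; full calibration takes on the order of a minute; a
10,000-iteration PSA a few seconds. The test suite runs the complete
acceptance surface, including a 10,000-draw PSA and an output-level
calibration round trip on synthetic targets, in a few minutes on one CPU.
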