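---
title: "An individual-level microsimulation of osteoporosis treatment cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-level microsimulation of osteoporosis treatment cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Postmenopausal women with osteoporosis (bone-mineral density T-score at or
below -2.5) face elevated risks of hip, clinical vertebral, wrist and other
osteoporotic fractures. Two bisphosphonate strategies are compared from the
healthcare-payer perspective of China (all costs in 2018 USD): weekly oral
alendronate (70 mg), which is cheap but poorly persisted with in the real
world, and once-yearly intravenous zoledronic acid (5 mg), which costs more
per year but makes a full year of exposure automatic at each infusion. The
output of the analysis is the lifetime discounted cost and quality-adjusted
life-year (QALY) difference between the strategies, summarised as an
incremental cost-effectiveness ratio (ICER), net monetary benefit
(NMB = WTP x dE - dC) and net health benefit (NHB = dE - dC/WTP) at a
willingness-to-pay (WTP) threshold of $29,340 per QALY — three times China's
2018 per-capita GDP.

Because medication persistence, compliance, and fracture history all shape an
individual's future risks, costs and utilities, a memoryless cohort Markov
model is inadequate. The package therefore implements an individual-level
state-transition model (microsimulation): women are simulated one at a time
through annual cycles from the starting age (65, 70, 75 or 80 in the base
case) until death or age 105, and tracker variables carry each woman's
fracture history and adherence clocks forward.

## States, trackers and the annual cycle

Every woman starts fracture-free. Within each one-year cycle, events are
evaluated in a fixed order:

1. **Adherence update.** At the treatment-year boundary a Bernoulli draw
   against the year-indexed persistence schedule decides whether a woman
   still on treatment continues. The last stated conditional continuation
   rate carries forward to any remaining treatment years (alendronate: 0.57
   at every boundary; zoledronic acid: 1.0 at entry, 0.73 at the year-2 and
   year-3 infusions).
2. **Death draw.** Annual background mortality at the woman's age band,
   multiplied after a hip fracture by an attenuated excess hazard (below).
   A woman who dies accrues no fracture, cost or utility in that cycle.
3. **Fracture draw.** A single categorical draw over hip, clinical
   vertebral, wrist, other fracture, or no event; at most one fracture per
   cycle. The per-type probability is the general-population incidence at
   the age band (per 1,000 person-years, used directly as an annual
   probability — all rates are far below 0.05, where the rate-to-probability
   conversion `1 - exp(-r)` differs negligibly) times the osteoporosis
   relative risk at that band, times the effective treatment relative risk.
4. **Tracker update.** Fracture counts (hip capped at two lifetime events,
   the others unlimited), the years-since-last-hip-fracture clock, the
   adherence clocks, and age.

All age-banded inputs are resolved by the woman's integer age at cycle
start, bands half-open `[lower, next)` with the last band open-ended (85+).

**Excess mortality.** Observed mortality after hip fracture is elevated by a
relative hazard of 2.87 within the first year and 1.73 thereafter, but only
25% of that excess is attributed to the fracture itself (the rest reflects
comorbidity of the women who fracture), so the model multiplies baseline
mortality by `1 + 0.25 * (RH - 1)`. Vertebral, wrist and other fractures
carry no excess mortality. After a second hip fracture the clock resets to
the first-year hazard, since recency of the most recent fracture drives the
risk.

## Adherence and the treatment effect

Two adherence dimensions are modelled separately:

* **Persistence** — remaining on therapy, handled by the annual Bernoulli
  draws above. A woman who abandons weekly oral alendronate during its first
  year does so mid-year: she accrues half a year of exposure, drug cost, and
  offset window. Later discontinuations, and all zoledronic acid
  discontinuations, happen at year boundaries (an infusion is either given
  or not).
* **Compliance** — the fraction of prescribed doses taken while persistent:
  0.71 for oral alendronate, fixed at 1 for the infusion. The realised
  relative risk reduction is assumed linear in compliance,
  `RR_eff = 1 - compliance x (1 - RR_trial)`, so full compliance recovers
  the trial efficacy and zero compliance leaves risk unchanged.

**Offset time.** After stopping, the anti-fracture effect washes out
linearly over a window equal to the time spent on treatment, anchored at the
compliance-scaled relative risk realised at stopping (residual benefit
cannot exceed realised benefit). Like every other cycle quantity, the decay
is evaluated from the state at cycle start: a woman who completed `T` years
receives fractions `1, 1 - 1/T, ..., 1/T` of her realised risk reduction
over the `T` cycles after stopping, and nothing thereafter.

Both treatment courses default to 3 years. The comparator's course is three
annual infusions; the alendronate course length is not an epidemiological
datum but an analysis choice, and is set equal so the strategies are
compared over the same intended course. It is an ordinary parameter field
(`treatments$alendronate$duration`) for anyone wishing to model longer oral
courses.

## Costs and utilities

Payer-perspective costs per cycle decompose into four components (an
accounting identity the test suite checks per cohort):

* **drug** — annual price times compliance while on treatment (a 6-month
  charge for mid-year first-year discontinuers of the oral drug);
* **monitoring** — one physician visit ($10), DXA scan ($85) and blood test
  ($72) per on-treatment year; not charged after discontinuation;
* **acute** — the one-time direct cost of the cycle's fracture (hip
  $7,103.25; vertebral $1,310.11; wrist $967.34; other $1,692.41);
* **long-term care** — $4,438.08 for every year lived in the post-hip
  fracture state, entered the cycle after a first hip fracture and kept for
  life, not double-counted after a second hip fracture.

Cycle utility is the age-band baseline multiplied by fracture multipliers:
first-year multipliers in the event cycle (hip 0.776, vertebral 0.724,
wrist 0.940, other 0.910) and subsequent-year multipliers for past hip
(0.855) and vertebral (0.868) fractures in every later year of life.
Multipliers for different fracture types combine multiplicatively; a repeat
fracture of one type applies that type's first-year multiplier alone. Wrist
and other fractures reduce utility in the event year only. Costs and QALYs
are discounted at 3% per year, `(1 + r)^(-t)` with the first cycle
undiscounted; the model applies no half-cycle correction (it is an
event-driven annual microsimulation, stated here as a deliberate choice).

## Common random numbers

All stochastic analyses pre-generate three uniform streams (death, fracture,
persistence) indexed by individual and cycle from the run seed, and reuse
them across strategies and across sensitivity-analysis reruns. Incremental
results therefore differ only through the treatment parameters: two
strategies with identical parameters produce bit-identical cohorts, varying
a cost-only parameter leaves the incremental effect bit-identical, and
tornado spans are not blurred by Monte-Carlo noise between bounds.

## Uncertainty analyses

* **One-way deterministic sensitivity analysis.** Every parameter with a
  published range is set to its lower and upper bound in turn (age-banded
  groups move jointly to their bound vectors, since the ranges are printed
  band-wise); the paired comparison is rerun and the ICER span tabulated as
  a tornado. Parameters printed with a range but no distribution (the
  excess-mortality hazards) participate here but are never sampled in the
  PSA.
* **Probabilistic sensitivity analysis.** Two-level: an outer loop draws
  every distributed parameter (beta and gamma moment-matched so the mean
  equals the published central value and the SD equals (upper - lower)/3.92,
  ranges read as approximate 95% intervals; triangular uses
  (lower, central, upper) as (min, mode, max); draws independent across
  parameters, with out-of-support draws redrawn), and an inner microsimulation
  produces one incremental cost/effect pair per draw. The cost-effectiveness
  acceptability curve reports, at each WTP value on a grid from 0 to 60,000
  in 1,000-dollar steps (always including 29,340), the fraction of draws
  with positive NMB.
* **Scenario analyses.** A: full persistence (all schedules set to 1);
  B: full compliance; C: both. Overrides apply to both strategies — the
  scenario asks what adherence itself is worth — and drug costs respond
  automatically because they are proportional to compliance and persistence.

## The synthetic parameter generator

`synthetic_parameter_set()` builds randomly generated but structurally valid
parameter sets with the same shape as the base case; the property tests rely
on its stress knobs: identical strategies (paired simulation must tie
exactly under common random numbers), zero incidence (no fractures can
occur), forced mortality 0 or 1 (trajectory length pinned to the horizon or
to one cycle), and scalable incidence, costs and between-strategy effect
gaps. It emulates the *structure* of real inputs — age-banded rates,
multiplicative risk modifiers, adherence schedules, distribution ranges —
not their epidemiology: synthetic rates are drawn uniformly, not calibrated,
so tests passing on synthetic sets certify the mechanics of the engine and
its invariants, not the realism of any particular projection.

## Numerical and design choices

* Beta/gamma hyperparameters are method-of-moments fits; the moment match is
  infeasible only if the implied variance exceeds `m(1-m)` for a beta, which
  the validator reports rather than silently clamping. Zero-width ranges
  collapse to the central value so degenerate specifications reproduce the
  base case exactly.
* Event ordering (death before fracture) is the simplest convention
  consistent with "at most one fracture per cycle"; a death cycle accrues
  nothing.
* The categorical fracture draw needs no normalisation at base-case
  magnitudes; the engine raises an error if the four probabilities ever sum
  above one (a parameter pathology, not a modelling state).
* Prior fractures do not modify subsequent fracture *probabilities* in the
  default configuration (multiplier 1.0); history enters through utilities,
  costs, mortality, and the hip cap. The per-type probability pipeline
  accepts effective-relative-risk matrices, so type-to-type risk multipliers
  can be layered on without touching the engine.
* Configuration files are JSON with 17-significant-digit doubles: a
  write/read round-trip reproduces every field bit-exactly, which the test
  suite asserts.

## Validation and problem sizes

`validate_model()` runs the no-intervention cohort and reports the lifetime
probability of a first hip and first clinical vertebral fracture and the
probability of death by 105, with Monte-Carlo intervals, against the
external benchmarks for Chinese women (11.099%, 39.693%, and ~99.0%
respectively at start age 65). With the packaged 5-year mortality bands the
model lands near 97.6% dead by 105 — slightly low, as expected when a
single-year national life table is coarsened to 5-year bands with an
open-ended 85+ band. The fracture validation quantities computed by this
implementation (about 15.0% hip, 36.5% vertebral at age 65; the package's
closed-form life-table oracle corroborates the simulation to Monte-Carlo
error) sit a few percentage points from those benchmarks: with the packaged
incidence, risk-adjustment and mortality tables, the benchmark pair is not
jointly reachable — lowering one moves the other further away — so the
numbers are reported as computed rather than calibrated to hit either one.

Default analysis sizes are 100,000 women per cohort for base-case and
validation runs and 1,000 x 10,000 for the PSA. The test suite exercises the
same code paths at reduced sizes chosen for desk-scale runtimes (20,000 per
strategy per age for decision-pattern checks, 10,000-20,000 per
sensitivity-analysis run, 100 x 1,000-scale PSA smoke runs); Monte-Carlo
standard errors at those sizes are small relative to every asserted margin,
and all sizes are ordinary function arguments.

## Limitations

* Payer perspective only; no productivity or informal-care costs.
* Women only, ages 65+; no screening strategies; no budget-impact analysis.
* Treatment efficacy is age-invariant, per the trial meta-analysis inputs.
* Persistence schedules beyond the printed years rely on the carry-forward
  rule; the mid-year discontinuation convention for the oral drug is a
  modelling choice matching its 6-month charging rule.
* The adverse-event profile of the infusion enters only through its annual
  cost; no pharmacology is modelled.
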