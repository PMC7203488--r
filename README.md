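# osteosim

An individual-level (Markov microsimulation) state-transition model for the
cost-effectiveness of anti-osteoporotic drug therapy in postmenopausal women,
parameterised for the Chinese healthcare-payer setting (2018 USD). The
packaged comparison is once-yearly intravenous zoledronic acid (5 mg) versus
weekly oral alendronate (70 mg) in osteoporotic women with no fracture
history, starting therapy at ages 65–80.

## Who this is for

Health-economic modellers who need a transparent, fully testable
microsimulation of osteoporosis treatment — every input is an ordinary R
object, every analysis is deterministic given its seed, and the engine,
adherence model and economics are exposed as composable functions rather
than buried in a GUI modelling tool.

## The model in brief

Women are simulated one at a time through annual cycles from the starting
age until death or age 105. Within a cycle: a persistence draw at the
treatment-year boundary, then a death draw (background mortality, inflated
after a hip fracture by `1 + 0.25 (RH − 1)` with RH = 2.87 in the first
year and 1.73 after), then a single categorical fracture draw over hip,
clinical vertebral, wrist and other fracture with per-type probability

```
P(fracture of type f at age a) = incidence_f(a)/1000 × RR_osteoporosis_f(a) × RR_treatment_f
```

Tracker variables carry fracture counts (hip capped at two), the hip-fracture
clock, and adherence clocks. The treatment effect while on therapy is the
trial relative risk scaled linearly by compliance,
`RR_eff = 1 − c (1 − RR)`; after discontinuation it decays linearly to 1
over an offset window equal to the time on treatment. Costs (drug ∝
compliance and persistence, monitoring, one-time fracture costs, lifelong
post-hip long-term care) and utilities (age-band baseline × fracture
multipliers) accumulate per cycle, discounted at 3%/year. Strategies are
compared as

```
ICER = ΔC/ΔE,   NMB = λΔE − ΔC,   NHB = ΔE − ΔC/λ,   λ = $29,340/QALY
```

with paired cohorts driven by common random numbers. One-way deterministic
sensitivity analysis (tornado), a two-level probabilistic sensitivity
analysis with cost-effectiveness acceptability curves, and full-adherence
scenario analyses are included. See the methods vignette
(`vignettes/osteoporosis-microsimulation.Rmd`) for the full model account.

## Worked example

```r
library(osteosim)

fit <- ce_microsim(n = 20000, seed = 42)   # 4 starting ages, paired arms
fit
```

```
Microsimulation cost-effectiveness analysis: zoledronic vs alendronate
  n = 20,000 per strategy per age, WTP = 29,340 USD/QALY
 age cost_reference cost_comparator delta_cost qaly_reference qaly_comparator
  65        6153.30         7110.54     957.25         10.095          10.134
  70        5583.41         6408.81     825.40          7.987           8.026
  75        4789.72         5526.97     737.24          6.144           6.183
  80        3833.01         4521.21     688.19          4.519           4.564
 delta_effect  icer label    nmb   nhb
       0.0390 24529  icer 187.76 0.006
       0.0387 21346  icer 309.09 0.011
       0.0397 18580  icer 426.95 0.015
       0.0450 15305  icer 631.10 0.022
```

Each row pairs the two strategies at one starting age under common random
numbers: at age 65 the infusion strategy costs $957 more and yields 0.039
more QALYs per woman over her lifetime, an ICER of $24,529 per QALY — below
the $29,340 willingness-to-pay threshold, so zoledronic acid is
cost-effective, and increasingly so at older starting ages (the ICER falls
monotonically to $15,305 at age 80 as hip-fracture risk rises).

Model validation against external epidemiological benchmarks:

```r
validate_model(ages = 65, n = 100000, seed = 42)
```

```
No-intervention validation runs
  start age 65 (n = 100,000):
    P(>=1 hip fracture)       = 14.861% +/- 0.220
    P(>=1 vertebral fracture) = 36.369% +/- 0.298
    P(dead by horizon)        =   97.7%
  benchmarks at start age 65: hip 11.099%, vertebral 39.693%,
  dead by 105 ~99.0% (single-year national life table; the model's
  5-year mortality bands give a slightly lower value)
```

The report prints the simulated quantities next to the benchmarks; the
vignette discusses why the packaged age-banded inputs land a few points away
from the fracture benchmarks and the 5-year mortality bands slightly below
the life-table death probability.

Other entry points: `simulate_individual()` (single lifetime trajectory),
`simulate_cohort()` (one arm), `one_way_dsa()` (tornado), `probabilistic_sa()`
and `ceac_from_draws()` (PSA/CEAC), `run_scenario()` (full persistence /
compliance), `write_parameters()` / `read_parameters()` (JSON configuration),
and `run_pipeline()` (configured runs with provenance-stamped output files).

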