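---
title: "Simulating peatland carbon accumulation and the near-surface artefact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating peatland carbon accumulation and the near-surface artefact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Peat cores record the mass and age of material a peatland has retained.
Dividing each layer's carbon content by its age span gives an *apparent*
carbon-accumulation rate, and such "accumulation histories" are widely used
to interpret past climate and, more recently, the effect of land management.
The apparent rate in near-surface peat is, however, systematically inflated:
young litter has not yet finished decomposing, so most of it will never join
the long-term store.  The same core can therefore show a near-surface gain
while the peatland as a whole loses carbon — for instance after ditch
drainage, when old, previously saturated peat is re-exposed to oxygen and
decays anew (secondary decomposition).

`peatsim` implements a cohort-based peatland development model on a
hydrologically coupled transect to reproduce and dissect both effects: the
intrinsic "hockey stick" in apparent rates, and the divergence between
near-surface apparent gain and whole-profile net balance under drainage.

## The model

### State

A peatland is a line of `n_cols` columns of width `dx` (default 75 × 2 m,
150 m from the dome centre to the margin) on a flat impermeable base.  Each
column is an ordered stack of *cohorts*: the litter added in one year,
tracked through time by

* current mass $m$ (g m⁻²) and initial mass $m_0$,
* thickness $m/\rho$ with a single dry bulk density $\rho$,
* hydraulic conductivity $k = k_s (m/m_0)^{c}$, which declines as the
  cohort decomposes,
* its deposition-year span (needed for age arithmetic after aggregation).

The margin column is a fixed-head (Dirichlet) boundary representing a lagg
stream; the centre boundary is no-flow (dome symmetry — the model simulates
half of a symmetric bog).

### Processes, in the order they run each simulated year

1. **Weekly hydrology (52 steps).**  The water table follows a
   Boussinesq-type lateral-flow equation: the storage change of each column
   balances the divergence of depth-integrated flow (transmissivity =
   conductivity integrated over the saturated profile) plus the week's net
   rainfall, divided by the drainable porosity.  Heads are capped at the
   peat surface — the excess leaves as runoff, which is why net rainfall is
   supplied weekly rather than annually: winter surplus must be allowed to
   run off rather than be implicitly stored for summer — and floored at the
   base.  Each cohort's weekly position relative to the water table is
   accumulated into an annual oxic-exposure fraction $f \in [0,1]$.
2. **Annual decomposition.**  Each cohort decays exponentially at a rate
   blended from the two end-members by its exposure,
   $\alpha = \left[f\,\alpha_{ox} + (1-f)\,\alpha_{an}\right]
   Q_{10}^{(T-T_{ref})/10}$,
   with the year's air temperature $T$.  Decay rates are constant per
   regime; the observed slow-down of decay with age *emerges* from burial
   below the water table rather than from an explicit recalcitrance term.
3. **Annual litter addition.**  Production responds unimodally to the
   annual-mean water-table depth (parabola with an optimum, zero beyond
   `wtd_optimum + wtd_range`, reduced under inundation) times a monotone
   temperature ramp equal to 1 at the reference temperature.  The new
   cohort becomes the column top.
4. **Thin-layer aggregation.**  Adjacent cohorts thinner than 2.5 mm lying
   entirely below the water table are merged (masses summed, deposition
   year mass-weighted, full year span retained).  Cohorts above the water
   table are never merged, preserving annual age resolution exactly where
   the 0–200-yr analysis windows need it.
5. **Ditch excavation** (drained scenario, once).  At the opening year the
   top 0.5 m of each ditched column is removed and the column becomes a
   fixed-head boundary at the new surface.  The ditch level does not track
   later subsidence, and ditched columns no longer receive litter.

### Analysis

A **virtual core** is the end-of-run cohort inventory of one column
(by default the centre–margin midpoint).  From it the package computes:

* the **apparent rate history**: for each sequential pair of records,
  $r = 0.5\,(m_i + m_{i+1})/2 / \Delta\mathrm{age}$, with the carbon
  fraction 0.5 and $\Delta$age taken youngest-to-youngest so merged records
  contribute multi-year denominators;
* **windowed mean rates** (0–200 and 200–600 yr by default), weighted by
  each entry's age span — entries represent unequal spans after
  aggregation, so a span-weighted mean is the faithful time average (the
  field's tables do not state which average they use; this choice is ours);
* **LORCA**, total carbon over basal age;
* the **net balance decomposition** over a tracked period (by default the
  final 200 years): remaining new material $N$, decay losses from the
  original acrotelm $A_o$ and original upper catotelm $C_s$ (split by the
  annual-mean water-table elevation at the period start, using record
  midpoints — the operational boundary is ours), and excavated mass $E$,
  closing exactly against the stock change.

## Parameters

Published configurations of models in this family defer their litter,
decay and conductivity constants to site-calibrated prior work, so the
defaults below are this package's own calibrated set.  They were chosen so
that the natural 6,000-year run yields a midpoint core of roughly 3.5 m
whose apparent-rate history shows ≈140 g C m⁻² yr⁻¹ in the 0–200-yr window,
≈30 g C m⁻² yr⁻¹ at 200–600 yr, and a millennial pre-industrial rate near
27 g C m⁻² yr⁻¹ — magnitudes typical of temperate raised bogs.

| parameter | default | units | role |
|---|---|---|---|
| `oxic_decay_rate` | 0.03 | yr⁻¹ | acrotelm end-member decay |
| `anoxic_decay_rate` | 8e-5 | yr⁻¹ | catotelm end-member (ratio 375:1; field estimates put the ratio at 100 or more) |
| `decay_q10`, `production_q10` | 2.0, 1.3 | – | temperature sensitivities, = 1 at 7.1 °C |
| `max_production` | 800 | g m⁻² yr⁻¹ | litter at the optimum water-table depth |
| `wtd_optimum`, `wtd_range` | 0.10, 0.50 | m | production parabola |
| `bulk_density` | 1e5 | g m⁻³ | converts mass to thickness |
| `k_surface`, `k_exponent` | 100, 3 | m wk⁻¹, – | fresh-litter conductivity and its decline with decomposition |
| `drainable_porosity` | 0.3 | – | specific yield |
| `carbon_fraction` | 0.5 | – | C per unit dry mass |
| `aggregation_threshold` | 2.5e-3 | m | thin-layer merging |

The calibration is a joint one: the acrotelm residence of a cohort (mean
water-table depth divided by the near-surface growth rate) times the oxic
rate sets how much litter survives into the catotelm, which in turn sets
both the long-term rate and, integrated over six millennia of slow anoxic
decay, the final height.  `k_surface` and the seasonal amplitude control
the water-table regime that closes this loop.

## The synthetic climate driver

The driver emulates a six-millennia annual reconstruction for a temperate
oceanic bog: AR(1) series for annual net rainfall (sd 10 cm, lag-1
autocorrelation 0.7) and air temperature (sd 0.5 °C, autocorrelation 0.7),
each shifted so the sample means equal 96.2 cm and 7.1 °C *exactly*,
mimicking the use of one fixed reconstruction.  Each year's rainfall is
spread into 52 weekly depths by a single seasonal pattern reused for every
year.  Because no observed weekly record is bundled, the default pattern is
a sinusoid (amplitude 2.0): winter weeks peak near 5.5 cm wk⁻¹ and
mid-summer weeks dip to about −1.8 cm wk⁻¹ (evapotranspiration exceeding
rainfall), a realistic seasonal contrast for northern England that produces
summer water-table drawdowns of a few decimetres.  An observed 52-week
record can be supplied through `derive_seasonal_pattern()`, whose weights
are week-over-annual-total shares — the one reading of a "proportional"
weekly pattern under which the stated multiplication by the annual value
returns depths that sum back to that value.

What the generator does **not** emulate: centennial climate trends or
events (the artefact tests deliberately include a zero-variance climate to
show the hockey stick needs none), sub-weekly weather, spatial climate
gradients, and any real proxy-based reconstruction.  Passing tests
therefore demonstrate internal consistency of the model's mechanisms, not
agreement with any particular field site.

## Numerical choices

* **Hydrology.**  Backward-Euler sub-steps (default 20 per week) with
  transmissivity lagged one sub-step, solved by the Thomas algorithm —
  unconditionally stable for any conductivity profile.  Face transmissivity
  is the arithmetic mean of the neighbours; for homogeneous conductivity
  this makes the discrete steady state satisfy the Dupuit relation
  $h^2(x) = H_b^2 + (P/K)(L^2 - x^2)$ exactly, which the test suite uses as
  an analytic oracle.  A non-finite solve reports the offending week.
* **Balances as invariants.**  Every run tracks per-column mass balance
  (litter − decay − excavation = stock change) and every weekly step closes
  a water balance (storage = recharge − runoff − boundary outflow +
  base deficit); both are enforced at 10⁻⁶ relative in randomized property
  tests.
* **Two engines.**  The compiled annual loop (`engine = "cpp"`) is the
  production path; `engine = "r"` composes the same loop from the exported
  R-level operations and agrees with it to ~10⁻⁹ on identical
  configurations, guarding the compiled code against drift from the
  documented operations.
* **Degenerate inputs.**  Heads are capped/floored with the excess logged;
  zero litter years add no cohort; a ditch deeper than the peat is an
  error; an empty analysis window raises a classed condition rather than
  returning 0.

## Design choices that were genuinely open

* "Proportional difference" for the weekly pattern is read as
  share-of-total (see above); the deviation-from-mean reading does not
  yield usable weekly depths by multiplication.
* The ditch removes only the top 0.5 m (consistent with "0.5-m-deep
  ditches") rather than the whole column, and its water level is fixed at
  the excavation-time surface.
* Decay runs annually on weekly-resolved exposure fractions; hydrology runs
  weekly.  This matches the stated time structure of the processes and
  keeps a six-millennia, 75-column run on a desk scale (roughly half a
  minute).
* Ages are referenced to a notional "present" at the end of the run; an
  annual cohort deposited in year $y$ of an $n$-year run spans ages
  $[n-y, n-y+1)$.

## Problem sizes

The standard configuration is 6,000 years × 75 columns with 52 weekly
hydrological steps per year.  The test suite exercises the full
configuration for the acceptance-style checks (three seeds for the natural
run, one paired drained run, one constant-climate run) and much smaller
randomized configurations (10–80 years, 4–12 columns) for the property
suites.  `scripts/acceptance.R` reruns the full natural configuration over
three seeds.

## Known limitations

* One bulk density for all peat: fresh near-surface litter is denser, and
  old catotelm peat lighter, than in reality; thickness-based statistics
  (e.g. the thickness of sub-200-yr peat) are the least constrained.
* No explicit recalcitrance, vegetation dynamics, peat temperature, methane
  or dissolved-carbon fluxes; the transect is 1-D (no radial plan-form).
* The ditch parameterization is deliberately simple: fixed level, no
  re-profiling, no maintenance cycle.
* The calibration targets magnitudes, not any specific site; parameter
  values should be re-estimated before quantitative use on real cores.

## A worked example

```{r example}
library(peatsim)

climate <- weekly_climate(generate_annual_series(seed = 1))
natural <- run_simulation(climate, seed = 1)
drained <- run_simulation(climate, ditch = ditch_plan(), seed = 1)

core <- virtual_core(natural)
history <- apparent_rate_history(core)
windowed_mean_rate(history, 0, 200)    # near-surface apparent rate
windowed_mean_rate(history, 200, 600)  # long-term rate: many times lower
net_balance_series(drained)            # net loss despite positive N
```
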