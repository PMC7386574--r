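---
title: "grassim: model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{grassim: model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`grassim` simulates a mown temperate grassland as a community of individual
plants on a 1 m x 1 m patch, in the tradition of forest gap models: plants
have sizes but no explicit coordinates, and all interactions act through
size-structured competition for light and through shared budgets of space,
soil water and mineral nitrogen. On top of the simulator sit the inverse
parameterization (fit species traits to observed vegetation patterns) and an
evaluation layer (replicate averaging, OLS regression, normalized RMSE,
relative yields). This vignette records the model equations, the assumptions
behind them, the defaults, and the design decisions taken where the design
was genuinely open.

## The plant and its geometry

A plant is a cylinder of height $h$ (cm) and diameter $w$ (cm) holding three
biomass pools (g organic dry matter): green shoot, senescent shoot and root.
The shoot (green + senescent) fills the encasing cylinder at an effective
tissue density, the shoot correction factor $f_s$ (g cm$^{-3}$):

$$B_{shoot} = f_s \tfrac{\pi}{4} w^2 h .$$

On the growth path height and width are isometric, $h = hw \cdot w$, with the
species height-width ratio $hw$; inverting the two relations gives
$w = (4B/(\pi f_s\, hw))^{1/3}$. Above the species maximum height $h_{max}$
the height is pinned and extra biomass widens the plant, which keeps the
biomass-geometry map single-valued and mass-conserving. After mowing a plant
is shorter than its isometric height; it then keeps its width and regrows in
height only ($h = B / (f_s \frac{\pi}{4} w^2)$) until the isometric relation
holds again. The cylinder therefore holds exactly the current shoot biomass
at all times, which is what makes the mowing harvest bookkeeping exact.

Ground (cover) area is the cylinder footprint $\frac{\pi}{4}w^2$; the
*exclusive* area — what the plant claims against the space budget — is the
footprint times the species overlapping factor $f_O$ ($f_O = 1$ for the two
grasses, 0.8 for the forb, so forb individuals may interleave). Leaf area is
`SLA` times the *green* shoot only; senescent shoot contributes mass and
height but no leaf area. Simulated aboveground biomass includes both shoot
pools (the field protocol does not distinguish them in a harvest). Rooting
depth follows the power law $r_1 B_{root}^{\,r_2}$; root length (`SRL`) is
carried in the trait set but unused by the simplified soil.

## Light competition and carbon balance

Each plant's leaf area is spread uniformly over its own height. The
extinction above height $z$ sums every plant's own Beer-Lambert coefficient
$k$ times its leaf area above $z$:

$$K(z) = \sum_j k_j \, \mathrm{LA}_j \, \max(0, h_j - z)/h_j \, / \, A_{patch},
\qquad I(z) = I_0 e^{-K(z)} .$$

Because the per-plant leaf area density is uniform, $K$ is piecewise linear
and the implementation evaluates it exactly at each plant's top via sorted
suffix sums (the fine-layer limit of a discretized canopy; the profile
returned to the user is gridded only for inspection). Ties in height do not
shade each other, so the profile is invariant to plant ordering.

The leaf light response is saturating,
$p(I) = \alpha I \, p_{max} / (\alpha I + p_{max})$, and integrating it over
a plant's own leaf area index $L = \mathrm{LA}/A_{cover}$ with within-crown
extinction $k$ and transmission $m$ gives the closed form

$$P_{area} = \frac{p_{max}}{k} \ln
  \frac{\alpha k I_{top} + p_{max}(1-m)}
       {\alpha k I_{top} e^{-kL} + p_{max}(1-m)}$$

in µmol CO$_2$ per m$^2$ of covered ground per second. Daily gross
production converts via covered area, day length, 44 µg CO$_2$ per µmol and
an organic-matter yield of 0.63 g ODM per g CO$_2$ (a long-standing gap-model
convention; configurable). Mean daytime irradiance is daily PAR divided by
day length — no diurnal cycle. The closed form is verified in the tests
against a 100-layer numerical integration of the leaf response for all three
species' $(p_{max}, \alpha, k, m)$ at a grid of LAI and irradiance values
(agreement within 0.5%).

Growth limitation is multiplicative: $GPP_{lim} = GPP \cdot f_T f_W f_N$
with a linear temperature ramp $f_T$ from 0 °C to 10 °C (both configurable)
and water/nitrogen factors described below. A smooth multiplicative form was
preferred over a Liebig minimum for continuity of the cost surface during
calibration. Maintenance respiration is $r_m$ (shoot green + root) per day;
the surplus pays growth respiration $r_g$; net production is split
`alloc_shoot` : (1 − `alloc_shoot`) between shoot and root. Green shoot
yellows into the senescent pool at rate $1/\mathrm{LLS}$, standing senescent
shoot falls to aboveground litter at a configurable rate (default 0.03
d$^{-1}$, i.e. roughly a month of standing dead tissue), and roots turn over
to belowground litter at $1/\mathrm{RLS}$. When $GPP_{lim} < R_m$ the
deficit is removed proportionally from the respiring pools (green shoot and
root); a plant whose pools cannot cover the deficit, or whose green shoot
falls below a starvation floor (default $10^{-4}$ g), dies. Per-plant carbon
closes exactly: change in pools + litter out + respiration = $GPP_{lim}$,
and the test suite asserts this to $10^{-9}$ under fuzzed inputs and
whole-system over full runs.

## Water, nitrogen and the limitation feedback

The full soil model of the parent framework is out of scope here; it is
replaced by single-layer buckets that preserve the interface a richer soil
model would use (a daily water supply and a daily nitrogen supply against
the community's demands). Water: plant-available storage with capacity 120
mm (default), filled by rain; bare-soil evaporation takes a fixed share
(default 0.3) of PET first; transpiration extraction is capped by what is
available; excess drains. Nitrogen: above/below litter pools decay at a
first-order mineralization rate (default 0.02 d$^{-1}$), releasing their
nitrogen (litter N = litter mass / `CN_sen`) into a mineral pool also fed by
atmospheric deposition (default 0.008 g m$^{-2}$ d$^{-1}$, a typical Central
European load); plant uptake is capped by the stock. Both balances close to
$10^{-9}$ by construction and by test.

Water demand of a plant-day is $GPP_{lim}/\mathrm{WUE}$ (kg water = mm on
the 1 m$^2$ patch); nitrogen demand is $NPP/\mathrm{CN}_{green}$. To avoid
an implicit within-day iteration, the supply/demand ratios act with a
one-day lag: today's growth uses yesterday's ratios. One subtlety matters
numerically: if the ratio were defined against yesterday's *realized*
(already-limited) demand, the feedback map would be $f_{t} = c/f_{t-1}$,
which has no damping and oscillates with period 2 between full growth and
no growth whenever the bucket runs dry. The ratios are therefore computed
against the *temperature-limited potential* demand (what the community would
transpire and take up if soil resources were unlimited), which makes the
fixed point stable while actual extraction remains the realized demand.
Supply never exceeds demand or stock in either formulation.

## Demography

Seed rain arrives from the surrounding landscape from julian day `t_meta`
(day 136) for a configurable window (default 120 days — the data constrain
only the start day), with daily germinating counts drawn as
Poisson(`N_seed_meta` × `germ_pct` × patch area). A cohort emerges `t_em`
days later as seedlings of height `h_min` on the isometric path, with root
mass set by the shoot-root ratio `sr`. Establishment respects the space
budget: seedlings establish only while the community's summed exclusive area
stays within the patch; the surplus is discarded and counted. Cohorts due on
the same day are processed in random order so that no species holds a
positional priority on free space — with deterministic ordering, two
identical species would drift apart systematically, which the
symmetric-mixture test would (and did, during development) expose.

Mortality is the model's only stochasticity besides seed counts and
establishment order. Each plant dies independently: below `age_rep` years
with the daily seedling rate `m_seed`, above it with the compounded daily
equivalent $1-(1-m_{basic})^{1/365}$ of the annual mature rate (compounding,
not division, so large rates stay exact). Crowding mortality triggers only
when the summed exclusive area exceeds the patch: victims are removed one at
a time, uniformly at random by default (`crowding_bias = "inverse_size"`
weights victims by inverse size instead), until the community fits. All
pools of dying plants flow to litter, so mortality conserves mass. `age_rep`
also gates optional internal reproduction, which is off by default:
recruitment is driven by external seed rain, as in the field setting the
trait tables describe.

Within a day the processes run in a fixed, documented order: seed rain,
emergence, light profile, photosynthesis and limitation, carbon update and
senescence, intrinsic/starvation mortality, crowding, soil water, soil
nitrogen, mowing (if scheduled), census (if scheduled).

## Mowing, censuses and patterns

Mowing cuts every plant taller than the blade (default 10 cm) down to the
blade, removing the same fraction of green and senescent shoot; width is
unchanged. Harvest equals removed shoot exactly, and mowing is idempotent.
The default schedule mows twice a year (20 June and 20 September; 11 July in
an establishment year). Censuses default to the eve of each mowing event —
field censuses are tied to harvests — and record, per species and for the
community: summed shoot mass per area (AGB), summed exclusive area as
percent cover, summed leaf area over patch area (LAI) and maximum plant
height. Annual aggregation takes the mean and the (min, max) range of the
censuses within each calendar year. From monoculture and mixture aggregates
the package assembles the ten standard community patterns (per-species
monoculture AGB/LAI/height/cover; mixture community LAI and height;
per-species mixture AGB and cover; and per-species relative yields of AGB
and cover, the mixture-to-monoculture ratios).

## Synthetic climate

Site drivers are not part of the package inputs, so a generator produces a
temperate lowland climate: temperature and PAR as mid-July-peaking sinusoids
with Gaussian noise (means 8.5 °C and 22 mol photons m$^{-2}$ d$^{-1}$,
amplitudes 9 °C and 18), rainfall as a two-state Markov occurrence chain
(wet-after-dry 0.3, wet-after-wet 0.55) with exponential amounts (mean 4.5
mm, about 660 mm yr$^{-1}$), PET as a non-negative sinusoid (mean 1.4 mm
d$^{-1}$), and day length from latitude 51° by standard solar geometry.
These values were chosen once as a realistic Central European regime. The
generator reproduces seasonality, wet/dry spells and interannual noise; it
does not emulate heat waves, snow, soil frost beyond the temperature ramp,
or correlated temperature-radiation anomalies. Tests passing under this
driver therefore demonstrate internal consistency and qualitative realism,
not site-specific prediction. All series are reproducible under a seed, and
the package works on a 365-day calendar (a Feb 29 in input data is folded
onto Feb 28).

## Inverse parameterization

Observed and simulated patterns are compared by MAPE
($\frac{1}{N}\sum |y-x|/|x|$, dimensionless) or nrmse
($100 \cdot \mathrm{RMSE}/\bar{x}$, percent); a combined criterion
$\mathrm{nrmse} + 100|1-s| + 100(1-R^2)$ (slope $s$ and $R^2$ from the OLS
regression of simulated on observed) is available as a third cost — its
exact weighting is a package convention. Multi-pattern costs are unweighted
sums by default. Because mortality is stochastic, each cost evaluation
averages a small number of simulator replicates (default 3); final
evaluations average many more (100 in the evaluation layer's intended use).
Costs can consume annual means (default) or the raw biannual censuses.

Three bounded derivative-free optimizers are provided. Dynamically
dimensioned search perturbs, at iteration $t$ of $T$, each dimension with
probability $1-\ln t/\ln T$ (at least one forced) by a Gaussian step of 0.2
times the bound range, reflected at the bounds, with greedy acceptance — the
search narrows from global to local as the budget is spent. Differential
evolution is rand/1/bin with $F = 0.8$, $CR = 0.9$. Simulated annealing uses
single-dimension Gaussian proposals under geometric cooling over three
decades from the initial cost scale; it stands in for adaptive variants,
whose reparameterized schedules are out of scope. All treat non-finite costs
as +Inf and are reproducible under a seed; accepted-cost traces are
non-increasing for the greedy methods.

Default trait boxes for the 16 inversely parameterized traits span broad,
biologically plausible ranges around the shipped values; the overlapping
factor can be added as a 17th free trait for forbs. The five "estimated"
parameters are ordinary fixed inputs here; which five they were is not
recoverable from the trait tables alone, so the reference column is taken as
authoritative.

## Problem sizes used by the test and acceptance experiments

These are the package's own choices of experiment scale, stated here so the
results are interpretable:

* Parameter recovery: a 6-year *F. pratensis* monoculture under the default
  synthetic climate; noise-free observations from a 16-replicate mean at
  biannual census granularity (the intra-annual June/September contrast is
  what separates leaf lifespan from the light-response parameters); four
  free traits ($p_{max}$, $\alpha$, LLS, `alloc_shoot`); DDS with $T = 500$
  and 3 simulator replicates per evaluation, repeated over 3 optimizer
  seeds, reporting the lowest-cost fit. The experiment recovers
  `alloc_shoot` and LLS and reaches a final multi-pattern MAPE at the
  stochastic cost floor, but it also exposes a structural compensation
  between $p_{max}$ and $\alpha$: the two light-response parameters can
  trade off along a valley in which the cost stays at its floor, so they
  are not individually identifiable from these four aggregate patterns at
  this evaluation budget and replicate noise level. This is a property of
  the patterns, not of the optimizer — direct probes of the cost surface
  find near-floor costs with $p_{max}$ off by tens of percent and $\alpha$
  compensating.
* Pattern-subset sensitivity: the same species over a 3-year horizon,
  comparing the four single-attribute cost specifications against the full
  four-attribute specification at $T = 200$, 3 seeds, nrmse evaluation on
  all four attributes from a replicate-averaged rerun.
* Symmetric-mixture relative yield: one species cloned into two identical
  species; the monoculture at full seed rain versus the two-clone mixture at
  half seed rain each, 6 years, 64 replicates; the relative yield of mean
  annual cover has expectation 0.5 by symmetry, and the experiment checks
  the simulator does not break that symmetry.

## Known limitations

* The soil is a deliberately minimal stand-in: no soil organic matter
  fractions, no soil temperature, single-layer hydrology, and rooting depth
  does not feed back on water access.
* Trait values are constant over a plant's life; no plasticity, no
  trade-off sampling, no seed bank, no clonal spread, no grazing or
  fertilization.
* The nitrogen-fixation flag is stored but inert (all three shipped species
  are non-fixers).
* Cover is exclusive-area based and so saturates near 100% whenever seed
  rain keeps the patch space-filled; sparse-canopy cover dynamics below
  that ceiling are driven by mortality and regrowth gaps.
* The one-day limitation lag means a single anomalously dry or N-poor day
  affects growth one day late; sub-daily dynamics are out of scope.
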