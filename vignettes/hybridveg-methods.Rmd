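---
title: "Modelling dryland vegetation patterns with hybridveg: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dryland vegetation patterns with hybridveg: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hybridveg` simulates water-limited vegetation as a hybrid of two
formalisms. The *soil* is a grid of square parcels, each holding two
continuous stocks: surface water $O$ (mm) and soil water $W$ (mm). The
*vegetation* is a population of discrete, individually tracked plants,
each with a continuous biomass $B_i$ (g), an age, a position, and a
running biomass maximum $B_{max,i}$. Water moves continuously; plants
grow continuously but reproduce and die as discrete stochastic events.

### Water dynamics

Per parcel, with $P = \sum_i B_i / \Delta x^2$ the biomass *density*
(g m$^{-2}$) of the plants standing on the parcel:

$$
\frac{\partial O}{\partial t} = R(t)
  - \alpha O \frac{P + k_2 W_0}{P + k_2} + D_O \Delta O, \qquad
\frac{\partial W}{\partial t} =
  \alpha O \frac{P + k_2 W_0}{P + k_2}
  - g_{max}\frac{W}{W + k_1} P - r_w W + D_W \Delta W .
$$

Rainfall $R(t)$ feeds surface water; infiltration transfers it to the
soil at a rate that saturates with vegetation density — bare soil
infiltrates only a fraction $W_0$ of the maximum — so plants improve
their own water supply. This *infiltration feedback*, combined with fast
surface-water diffusion ($D_O \gg D_W$), redistributes water laterally
toward vegetated parcels and is the engine of pattern formation: spots,
labyrinths and gaps emerge along a rainfall gradient. Soil water is lost
to evaporation/drainage ($r_w W$) and plant uptake (Michaelis–Menten in
$W$, linear in $P$).

Two readings of the infiltration denominator circulate in this model
family; we use the biomass-saturating form above (the one under which
bare-soil equilibrium is exactly $O = R/(\alpha W_0)$, $W = R/r_w$) and
keep the soil-water-denominator variant available as
`infiltration_denominator = "water"` for sensitivity analysis.

### Plant metabolism

Each plant obeys

$$
\frac{dB_i}{dt} = B_i\, b\, g_{max}\left(1 - \frac{B_i}{K_p}\right)
  \frac{W}{W + k_1} - B_i\, d ,
$$

reading $W$ from its own parcel only (no multi-parcel rooting). Growth
is water-limited and size-capped; turnover $d$ acts unconditionally, so
plants shrink wherever $\frac{W}{W+k_1} b\, g_{max} (1 - B/K_p) < d$.
For small plants this defines a soil-water survival threshold
$W^* = d\,k_1/(b\,g_{max} - d) = 4.5$ mm at the defaults; larger plants
need progressively wetter soil. Water drawn from the parcel is
proportional to raw biomass even when growth is size-capped — an
asymmetry we preserve deliberately.

### Life cycle

Discrete events run once per event step $\Delta t = 0.2$ d, after the
continuous block:

* **Reproduction.** A plant of age $\ge m$ produces seeds at expected
  rate $B_i\, s\, f(m)$ per day with $f(m) = l/m$ for $m > 0$ and
  $f(0) = 1$; the printed rate is realized as a whole part plus a
  Bernoulli remainder. The factor $l/m$ keeps expected lifetime
  fecundity roughly constant as maturity is delayed; $f(0) = 1$ removes
  the singularity of $l/m$ at the default $m = 0$.
* **Dispersal.** Direction uniform on $[0, 2\pi)$; distance lognormal
  with *mean* `mu_disp` (location $\ln\mu - \sigma^2/2$) — a leptokurtic,
  short-range kernel (median $\approx 3.25$ m at $\mu = 10$, $\sigma =
  1.5$) typical of arid-land taxa. Seeds landing outside the plot are
  lost (absorbing boundary).
* **Establishment.** A seedling roots with $B = 1$ g, age 0, unless the
  target parcel's biomass density exceeds $K_a$; seedlings landing in
  the same parcel in one step establish in randomized order, each adding
  its gram before the next is checked. The optional
  `preemptive_seedling_removal` flag additionally rejects seedlings whose
  instantaneous growth rate would be non-positive; it is **off** by
  default because the shortcut measurably distorts pattern formation
  (conditions at the landing point can improve after establishment).
* **Death.** Once $B_i/B_{max,i}$ drops below the threshold $d_b$, the
  plant dies with daily probability $1 - B_i/(d_b B_{max,i})$. An
  independent age hazard $1/l$ (exponential lifetime with mean $l$)
  represents senescence; a hard cutoff at age $l$ is available as
  `age_mortality_mode = "cutoff"` for sensitivity analysis. Daily
  probabilities convert to the event step by complement exponentiation,
  $p_{step} = 1 - (1-p_{day})^{\Delta t}$, which stays in $[0,1]$ for
  any step size.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `b` | water-to-biomass conversion | 10 | g mm$^{-1}$ m$^2$ |
| `g_max` | maximum water uptake | 0.05 | mm m$^2$ g$^{-1}$ d$^{-1}$ |
| `k1` | uptake/growth half-saturation | 3 | mm |
| `Kp` | plant size limiting factor | 800 | g |
| `d` | biomass turnover | 0.3 | d$^{-1}$ |
| `l` | mean life expectancy | 365 | d |
| `d_b` | stress-death threshold ratio | 0.8 | — |
| `m` | reproductive maturity | 0 | d |
| `s` | biomass-to-seedlings factor | 0.002 | seeds g$^{-1}$ d$^{-1}$ |
| `mu_disp` | mean dispersal distance | 10 | m |
| `sigma_disp` | kernel shape (log-sd) | 1.5 | — |
| `K_a` | establishment density cap | 30 | g m$^{-2}$ |
| `alpha` | maximum infiltration rate | 0.1 | d$^{-1}$ |
| `k2` | infiltration saturation constant | 5 | g m$^{-2}$ |
| `W0` | bare-soil relative infiltration | 0.15 | — |
| `r_w` | evaporation and drainage | 0.2 | d$^{-1}$ |
| `D_O` | surface-water diffusion | 10 | m$^2$ d$^{-1}$ |
| `D_W` | soil-water diffusion | 0.01 | m$^2$ d$^{-1}$ |
| `dx` | parcel side | 4 | m |
| `dt_event` | event step | 0.2 | d |
| `dt_int` | RK4 sub-step | 0.02 | d |

### Two calibration choices that matter

**Biomass enters the water equations as a density.** The infiltration
and uptake constants ($k_2$, $g_{max}$, and the cap $K_a$) are
calibrated on the g m$^{-2}$ scale used throughout the grid-hydrology
literature this model builds on. Feeding raw per-parcel grams into those
terms instead makes a single adult plant's nominal water demand exceed
several parcels' worth of rainfall, saturates the infiltration feedback
at seedling biomasses, and — we verified empirically — collapses the
model to a patternless carpet of stunted plants. With densities, a plot
water budget of realistic magnitude emerges and patterning is robust.

**Evaporation/drainage `r_w = 0.2` d$^{-1}$.** The bare-soil equilibrium
soil water is $R/r_w$. Pattern formation requires bare soil to be
inhospitable (below $W^* = 4.5$ mm) at the dry end of the rainfall range
and hospitable at the wet end; with $r_w = 0.2$ the crossover sits at
$R = 0.9$ mm d$^{-1}$, placing spots below ≈0.9, labyrinths near 1.3 and
near-uniform cover at 1.7 — the canonical sequence — and the plot-scale
water budget (rain = evaporation + uptake) closes at realistic standing
biomass. Halving it to 0.1 pushes the crossover to $R = 0.45$, outside
the studied range, and again yields uniform carpets everywhere. $0.2$
d$^{-1}$ is also the value used by the established grid-hydrology models
of this family.

## Numerics

* **Integrator.** The water fields and all plant biomasses are advanced
  *together* by classical RK4 with shared sub-steps (`dt_int`), the
  per-parcel biomass density refreshed at every stage. The default
  `dt_int = 0.02` d is far inside the stability region (the stiffest
  rate, surface diffusion, has $h\lambda \approx 0.1$) and halving it
  changes a 10-day solution by less than $10^{-4}$ relative. The
  experiment presets use `dt_int = 0.1` d: still stable
  ($h\lambda \approx 0.5$), and the 5-year demographic outcome is
  unchanged to printed precision relative to 0.02, far below replicate
  spread.
* **Splitting mode.** `coupling = "split"` integrates plants against
  frozen soil water and then water against frozen biomass, one event
  step at a time. The splitting error is secular during strong growth
  (a few percent per month at $\Delta t = 0.2$ d, shrinking with the
  step); co-integration is therefore the default, and the split mode is
  kept for numerical comparison.
* **Clamping.** Any negative stock produced by a sub-step is clamped to
  zero and counted (`n_clamps` in the output); in ordinary runs the
  count is zero.
* **Boundaries.** Water diffusion uses zero-flux (reflecting) boundaries
  by default, making the plot a closed hydrological unit whose water
  budget can be audited exactly; periodic boundaries are available.
  Seeds, in contrast, are lost when they cross the plot edge — the plot
  leaks propagules but not water.
* **Event scheduling.** Within one event step the order is: continuous
  block, then seed dispersal and establishment, then death, then aging.
  "Asynchrony" of the discrete events is implemented as independent
  per-plant draws in randomized order within the step; halving
  `dt_event` (a deterministic comparison with reproduction and death
  switched off) changes a 120-day outcome by under 5%.
* **Reproducibility.** One root seed drives everything (R's RNG is used
  from compiled code too); identical seeds give bit-identical runs. The
  hydrology consumes no randomness, so output toggles never shift the
  event stream.

## Initial conditions and what the generator emulates

`init_population()` implements two founding geometries: `"random"`
(uniform scatter) and `"aggregated"` — plants grouped in patches that
together cover 1% of the parcels (`ceiling(0.01 nx ny)` parcels,
partitioned among `n_patches` contiguous blocks grown from uniformly
chosen seed parcels; plants assigned round-robin among patches). Founding
biomasses are uniform in 1–2 g by default (the pattern preset fixes 1 g)
and ages uniform on 1–`l` days, avoiding an artificial death/reproduction
synchrony in the founding cohort. The soil starts at the bare-soil
equilibrium, so all early dynamics are attributable to the plants.

These initial states emulate a colonization scenario, not a surveyed
field site: real drylands carry soil heterogeneity, topography-directed
runoff, rainfall as discrete storm events, and seed banks, none of which
are modelled (surface routing is isotropic diffusion; rainfall is a
smooth daily rate). Passing the package's tests therefore demonstrates
internal consistency and reproduction of the *mechanisms* — patterning
along a rainfall gradient, dispersal-distance effects, shift and
seasonality responses — not calibration to any particular field system.

## Experiment presets and problem sizes

The `exp*` functions reproduce four virtual experiments at full scale
and at a desk scale (`scale` shrinks the plot side; plant and patch
counts shrink with the area so densities are preserved):

* `exp1a_precip_sweep()` — pattern morphology across constant rainfall,
  400 × 400 m, 1000 plants, 5 years, `s = 0.002`, fixed 1 g founders.
* `exp1_demography()` — population structure across rainfall,
  200 × 200 m, 250 plants in 25 patches, 5 years, `s = 0.001`.
* `exp1b_trait_sweep()` — dispersal distance (1–100 m) or maturity
  (0–240 d) sweeps on the demographic design. The trait sweeps run at a
  fixed 1.3 mm d$^{-1}$ — the baseline of the climate-change experiments
  and the labyrinth regime of the rainfall sweep.
* `exp2a_shift()` — growth at 1.3 mm d$^{-1}$ for 1500 d, then a step to
  0.8 with the age hazard disabled, assessed 365 d after the shift
  (the reported lag of visible effects is about a month; the 1-year
  assessment point is this package's choice of a "stabilized" state).
  `exp2a_viability()` sweeps shift amplitude and timing.
* `exp2b_seasonal()` — sinusoidal rainfall $1.3 + A\sin(2\pi t/365)$
  (phase 0 at $t = 0$), 12 years, summarized over the last 4 years,
  with a periodogram-based dominant-period detector for limit cycles.
  `ring_preset()` packages the high-resolution single-patch scenario
  (50 × 50 m at 1 m parcels, short dispersal, rain oscillating between
  1.0 and 1.6 mm d$^{-1}$) in which expanding ring patterns can emerge;
  it is provided as a qualitative scenario only.

The test suite runs the demographic design at its stated 200 × 200 m
with 5 replicate seeds, and the shift, trait and seasonal designs at
half linear scale with 2–5 replicates; the acceptance script
(`scripts/acceptance.R`) runs the demographic and shift designs at full
scale with 5 replicate seeds. These sizes keep a complete run on one
desktop core in the tens of minutes while leaving the reported
statistics dominated by replicate-to-replicate spread, not by plot size.

## Spatial statistics

Quadrat counts over an exhaustive square tiling (default quadrat = the
4 m parcel; the original analyses' quadrat configuration is not
recoverable, so absolute index values should be compared cautiously)
feed two classical dispersion indices computed with the sample
($n-1$) variance: Lloyd's index of patchiness
$IP = 1 + (s^2 - \bar m)/\bar m^2$ (1 under a Poisson pattern;
density-robust) and the David–Moore index of cluster size
$ICS = s^2/\bar m - 1$ (0 under Poisson; grows with absolute crowding).
The two are linked by $ICS = (IP - 1)\bar m$, which the package exploits
as an internal cross-check. `structure_summaries()` provides age and
biomass histograms (1 d / 1 g bins), means, seedling fraction (age
under 30 d) and density; `mortality_by_class()` tallies per-class death
fractions between two id-stable population states, with classes for the
0–1 g and 1–7 d cohorts.

## Known limitations

* Plants draw water only from their own parcel; at metre-scale parcels
  the absence of root spillover would bias growth of large plants.
* A single soil layer, no slope or directed runoff, no interception or
  evapotranspiration partitioning.
* The establishment cap uses the target parcel alone as the
  "surrounding area"; coarser or finer neighbourhoods would shift the
  cap's bite.
* Standing stocks of water-stressed ("doomed") seedlings are sensitive
  to the corridor soil-water level sitting near the survival threshold
  $W^*$; population *counts* are therefore less robust across
  parameterizations than biomass, cover and the direction of the
  experimental responses.
* The maturity compensation $f(m) = l/m$ is one defensible reading of a
  rate that is singular at the default $m = 0$; maturity-sweep results
  should be read qualitatively.
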