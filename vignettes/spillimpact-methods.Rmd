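---
title: "Methods: spill trajectories, oil fate and health impacts at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spill trajectories, oil fate and health impacts at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spillimpact` models the immediate public-health consequences of a
catastrophic tanker oil spill in a semi-enclosed sea: where the oil goes,
how fast it weathers, how much fine particulate matter (PM2.5) the spill
releases into the air, how much hospitalisation risk that exposure implies
for the coastal population, and which ports, desalination plants, food-aid
routes and fisheries are disrupted. Every stage runs on synthetic
environmental and demographic inputs generated inside the package, so the
entire chain is reproducible and testable on one machine with no data
downloads.

This vignette documents the models, their assumptions, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic setting can and cannot show about real events.

## The synthetic environment

Real assessments of this kind force their models with reanalysis winds
(hourly, ~0.25 degrees) and ocean-model surface currents. A desk-scale
artifact must emulate the *statistical structure* of those products rather
than their history. `generateEnvironment()` draws each field as

> seasonal mean + AR(1)-in-time, spatially smoothed Gaussian perturbation,

on a regular `(time, lat, lon)` grid (`GridSpec`). The AR(1) coefficient
(default 0.9 per hour) sets temporal persistence; the innovation scale sets
the marginal standard deviation (2 m/s per wind component, 0.08 m/s per
current component); an isotropic Gaussian kernel (2 cells) makes
perturbations spatially coherent. The kernel is normalised so white noise
keeps unit variance, which makes the configured marginal standard deviation
and lag-1 autocorrelation recoverable from samples — a property the tests
verify at n = 10,000.

The study region is an idealised two-coast channel whose axis runs roughly
north-north-west to south-south-east, with land on both sides
(`channelLandMask()`). The seasonal means encode the region's monsoon-driven
reversal: the **summer** mean flow points southeast along the axis (current
(0.04, -0.13) m/s, wind (1.0, -3.2) m/s) and the **winter** mean flow points
north (current (0.02, 0.13), wind (0.8, 3.2)). These are typical axial
surface-current and wind magnitudes for the region; with them, summer
ensembles drift southeast and winter ensembles north, which is the
qualitative seasonality the downstream estimators need to see. Wind speeds
are capped at 40 m/s and currents at 3 m/s. The spill source sits a few
nautical miles off the eastern coast, between the two key aid ports, as the
real stricken tanker does.

Population (`generatePopulation()`) is a Gaussian-kernel mixture around
coastal hotspot cities, restricted to land cells, and rounded by the
largest-remainder method so the grid sums *exactly* to the requested total
(8 million by default in the pipeline). The asset layer
(`syntheticAssets()`) provides two key aid ports on the eastern coast with a
joint 68% food-aid share, a southern port outside the channel, five
desalination plants (the eastern country's capacities unknown, to exercise
the equal-division rule), a fishery-yield grid over the eastern half of the
channel, and monthly fuel-import, price and food-assistance series sized
like the real region's.

What this emulation does **not** contain: real coastline geometry, tides
(excluded by design; the region's tidal range is small), wave turbulence,
mesoscale eddies, or historically dated events. Passing tests therefore
demonstrate that the algorithms are correct and the pipeline behaves
sensibly under realistic statistical forcing — not that the numbers
reproduce any particular historical hindcast.

## Spill transport

`runSpillSimulation()` is a GNOME-class Lagrangian surface-oil model.
Particles are sizeless carriers of a surface-thickness contribution,
released uniformly over the spill duration (default 168 h, a 7-day leak; 24
h is the fast variant) and stepped with forward Euler at `dt_min = 15`
minutes:

* **advection**: displacement = (current + windage x wind) x dt, converted
  to degrees with the local metres-per-degree; windage is drawn per particle
  from U(1%, 4%) at release and kept for life (the standard operational
  range);
* **diffusion**: independent Gaussian jumps per axis with variance 2 D dt,
  D = 10 m^2/s by default (10^5 cm^2/s, a standard horizontal diffusivity);
* **beaching**: a particle whose proposed position falls on a land cell is
  anchored at its last water position forever (no refloating);
* **domain exit**: particles leaving the gridded fields freeze with status
  `out_of_domain` and are excluded from concentration fields but retained in
  the particle accounting.

Forward Euler at 15 minutes is adequate because the forcing is
piecewise-constant at the field resolution (hourly) and the advection oracle
test bounds the error against the closed-form trajectory at <0.1%.

Each simulation also carries **uncertainty particles**: a parallel ensemble
whose currents and windage are scaled by a per-simulation multiplier drawn
from U(1.0, 1.5) and whose diffusivity is doubled. This is an explicit,
documented stand-in for operational "extreme weather" perturbation settings,
whose exact values are not public. The convex hull of all uncertainty
particles over all simulations (`uncertaintyRegion()`, via `chull`) is the
region in which roughly 90% of trajectories are expected to fall; by
construction it contains 100% of the uncertainty particles, which the tests
assert.

`runSpillEnsemble()` varies the spill start time uniformly over the field's
feasible range (date and time of day), grids weekly snapshots at
`decimals`-rounded coordinates (3 decimals is roughly 100 m, 2 roughly 1.1
km), and averages per-cell sums across simulations, counting zero for
simulations that missed a cell while leaving never-touched cells absent.
`percentileTransform()` converts mean thickness to percentile ranks among
exposed cells — "fraction of exposed cells with value <= x" x 100, ties
sharing the highest rank — because the absolute spilled volume is uncertain
while relative exposure is robust; the transform is invariant under
monotone rescaling. `interpolateBilinear()` provides values between cell
centres, treating absent neighbours as zero.

The footprint passed to asset estimators is **cumulative**
(`accumulateFields()`): a cell counts as reached once oil has been present
at any week mark, carrying its maximum weekly value. This makes
footprint-based series (fishery loss, plant disruption) monotone as the
spill grows, which an instantaneous snapshot would not guarantee once
floating oil moves on.

## Oil fate

`runFateOnce()` tracks hourly mass fractions over at most 144 h (six days;
longer horizons would need biodegradation and photo-oxidation, which the
model deliberately omits). The oil is a pseudo-component table; the default
"light-crude-like" table is light 55% / medium 25% / heavy 20% with
reference rates k = (0.028, 0.0015, 0) per hour. Each component depletes
first-order,

dm_i/dt = -k_i f(U, SST) m_i,  f = (1 + 0.045 U) x 2^((SST - 15)/10),

integrated *exactly* per step (`m exp(-k f dt)`), so the single-component
run reproduces 1 - exp(-lambda t) to floating point at any step size. The
modifier doubles evaporation per 10 C (Q10 = 2) and accelerates it linearly
in wind speed, the two dependencies any weathering calculator encodes; at
29 C and a 5 m/s wind the default table evaporates roughly half the oil in
24 h, the calibration anchor chosen for a light crude in warm water. That
anchor is a calibration, not a validation claim: the real oil's property
table is not public.

Clean-up (`cleanupConfig()`) models an optimistic response at printed
operational parameters: a skimmer recovering 14 bbl/h at 100% efficiency
(exactly 2,016 barrels over 144 h, an arithmetic the tests pin), 15% of the
oil sprayed with dispersant at 20% efficiency spread linearly over the first
48 h, and in-situ burning over 70,000 m^2 at 50% efficiency. Burning needs
one modelling decision: at the literature burn rate of 3.5 mm of slick
thickness per minute, a *continuously* fed 70,000 m^2 burn would consume
thousands of tons per hour and the whole spill within a day — inconsistent
with any large-spill response record, where burns are short episodic events
inside towed booms. Burns are therefore ignition events
(`burn_events_per_day`, default 1) each consuming the ignited slick
thickness (default 10 mm) over the contained area; the burn rate governs the
event's duration (minutes), not the daily total. With the defaults, six days
of clean-up removes roughly 300 t per burn event, 275 t by skimming and
4,500 t by dispersant — a few percent of a 150,000 t spill, matching the
scale of historical six-day recoveries. Removals are taken proportionally
across pseudo-components and capped so floating mass never goes negative;
mass is conserved to 1e-9 at every step, and under identical weather the
cleaned run never floats more than the weathering-only run.

`runFate()` wraps this in Monte Carlo over weather draws
(`fateWeatherDraws()` samples start times from the gridded fields) and
summarises each compartment by mean and 2.5th/97.5th percentiles.

## Atmospheric dispersion

`disperse()` replaces a full atmospheric transport system with a
single-layer Lagrangian model that preserves the assessment's computational
structure: 2,500 particles per start time, releases every 3 hours across the
season, 144-hour runs, and 24-hour averaging. Spilled oil mass is converted
to PM2.5 at a configurable rate — evaporative 0.008 ug/ug, plus 0.05 ug/ug
in fire mode — and emitted at sea level from the spill site over 24 h
(fast) or 72 h (slow). The published conversion-rate source is cited but not
printed in the assessment literature this package parallels, so these are
documented placeholder defaults carrying a standard deviation (0.002) for
the Monte Carlo. Particles ride the 10-m wind plus Gaussian turbulent
velocities (sigma = 0.5 m/s per axis) and mix uniformly over a fixed
boundary-layer depth (800 m); the concentration in a cell is in-cell
particle mass / (cell area x mixing depth). The headline field is the 24-h
average over the final day of the release; day-resolved averages feed
person-day accounting. The mass audit — emitted = in-domain + out-of-domain
— is exact, and concentrations are linear in the conversion rate, which the
uncertainty propagation exploits by rescaling a single base field per draw.

Emission from the fixed spill site (rather than from wherever oil drifts)
biases coastal exposure slightly downward; the single mixed layer ignores
vertical structure and deposition. Both simplifications are deliberate and
shared with the assessment this package parallels at the structural level.

## Health impacts

The exposure-response chain lives in `riskFunction()`,
`populationWeightedIR()`, `personDays()` and `propagateUncertainty()`:

* **Risk function.** Log-linear by default (standard in PM2.5
  epidemiology): IR(c) = 100 (exp(beta c) - 1) with
  beta = ln(1 + slope/100)/10, where `slope` is the percent increased risk
  of cardiovascular/respiratory hospitalisation per 10 ug/m^3. A linear
  form is available. The `burnett-style` default slope, 1.1573% (95% CI
  1.0825-1.2145), is calibrated so that 1,600 ug/m^3 — the level faced
  next to the slick by clean-up workers — corresponds to a 530% (460-590%)
  increased risk; the steeper `wei-style` and shallower `kloog-style`
  presets are sensitivity settings with user-replaceable values, since the
  underlying cohort coefficients are cited rather than printed in the
  sources this model parallels.
* **Population weighting.** PM2.5 is interpolated bilinearly to the
  population grid; IR is averaged over cells at or above the exposure
  threshold (10 ug/m^3), weighted by the exposed population only.
* **Person-days** sum population over cells and days with daily-average
  concentration at or above the threshold, over the release window (spill
  duration = exposure duration).
* **Uncertainty propagation.** Per draw, the slope is sampled as a relative
  risk per 10 ug/m^3 from Normal(mean, sd) with
  sd = ln(CI_upper/CI_lower) / (2 qnorm(0.975)) (`sdFromCI()`), and the
  conversion rate from Normal(mean, sd). Two truncation rules apply, both
  documented: negative sampled slopes and conversion rates are truncated at
  zero per draw, and a final lower uncertainty bound below zero is reported
  as 0 with the scenario flagged `possibly_null`. With enough mass below
  zero the reported interval becomes "(0, x)" exactly, the pattern real
  winter scenarios produce when plumes can miss the population entirely.
  Person-day uncertainty propagates both parameters (the conversion rate
  moves the threshold exceedance; the slope does not affect person-days).

Quantiles are *always* type-7 linear-interpolation sample quantiles
(`linearQuantile()`), one convention applied uniformly to fate bands, IR
intervals, person-days, fuel and food-aid series.

## Supply impacts

Each estimator is a small, fully specified computation:

* `portExposure()`: bilinear percentile at the port; `reached` (any oil)
  is the port-closure criterion, `exposed` (>= 90th percentile) the
  "directly impacted" designation. A `radius_deg` option (pipeline: 0.05
  degrees) lets a port count oil within its harbour extent, because a
  desk-scale ensemble's sparse 1-km cells leave single-cell gaps a point
  query would fall through; the default remains a pure point query.
* `desalDisruption()`: plants with any oil at their intake are disrupted;
  plants with unknown capacity receive an equal share of their country's
  total (conserving it exactly); disrupted capacity / per-capita daily use
  gives population equivalents.
* `fuelDisruption()`, `foodAidDisruption()`: mean and type-7 95% intervals
  of the monthly series; food aid multiplies the disrupted ports' combined
  share by the series statistics (share x quantile, the documented order).
* `priceSpike()`: percent change of the median price across fuel types
  between two dates.
* `fisheryLoss()`: regional yield summed over cells reached by the spill,
  with cells below the 10th percentile of surface concentration excluded by
  default to drop trace amounts (no threshold and the 20th percentile are
  sensitivity settings); thresholds are applied to the percentile-transformed
  field, and oil cells are co-registered to the yield grid by nearest cell.

## The pipeline, problem sizes and determinism

`runPipeline()` chains environment -> transport -> fate -> dispersion ->
health -> impacts and writes CSV/GeoJSON outputs plus a manifest of MD5
checksums. Per-stage seeds derive from the global seed by a small
deterministic hash of the stage name (`stageSeed()`), so stages can be
re-run in isolation; identical configuration and seed give identical
checksums.

The default configuration runs the whole chain in about a minute on one
CPU: 20 spill simulations x 150 trajectory + 150 uncertainty particles over
21 days at 15-minute steps per season, gridded at the ~1.1 km (2-decimal)
resolution variant (desk-scale ensembles are sparser than operational
thousand-simulation ones, so the coarser of the two published grid variants
is the pipeline default); 200 weather draws for the fate ensemble; 500
dispersion particles x 4 start times x 96 h per scenario; 400 Monte Carlo
draws per health scenario. All counts are configuration values; the
operational-scale defaults (1,000 simulations, 1,000 particles, 2,500
dispersion particles, 1,000 draws) remain the per-module defaults of
`trajectoryConfig()`, `disperse()` and `monteCarloConfig()`.

## Numerical choices and degenerate inputs

* Exact exponential evaporation update (no Euler error in the analytic
  limit); removals capped at floating mass; conservation asserted at 1e-9.
* Round-half-even coordinate rounding for gridding, matching R's `round()`.
* Bilinear interpolation clamps at field edges for dense grids and treats
  absent sparse cells as zero; queries outside the populated bounding box
  (padded one cell) are errors, and asset estimators catch them as
  "outside domain / unexposed" rather than failing.
* Convex hulls require >= 3 distinct non-collinear points; collinear input
  is a degenerate-geometry error.
* Zero-variance Monte Carlo inputs collapse uncertainty intervals onto the
  mean exactly; `n_mc < 2` is an error.
* The gridded-field JSON container writes doubles at 17 significant digits,
  so write/read round trips are bit-exact; the reader validates variable
  presence and units and normalises descending latitude axes.

## Known limitations

The package is a desk-scale structural reproduction, not an operational
forecast system. Its absolute outputs depend on synthetic forcing and
placeholder conversion/risk coefficients and should be read as
demonstrations of the method; the published numbers of any particular
historical assessment additionally depend on proprietary or unpublished
inputs (reanalysis history, oil property libraries, population rasters,
cohort coefficients) that no re-implementation can recover from the open
literature alone. Within that scope, everything the package asserts about
itself — conservation laws, analytic limits, oracle equalities, monotone
structure, seasonal direction, determinism — is enforced by its test suite.
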