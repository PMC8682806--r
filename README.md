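# spillimpact

Stochastic oil-spill trajectories, weathering and public-health impact
assessment for a catastrophic tanker spill in a semi-enclosed sea — the
whole chain from gridded winds and currents to hospitalisation risk and
supply disruption, runnable and testable on one machine with no external
data.

## Who this is for

Modellers and analysts who need a transparent, seed-reproducible
implementation of the standard spill-assessment chain:

1. **Lagrangian spill trajectories** — particle ensembles advected by
   surface currents plus 1–4% windage, with random-walk diffusion
   (variance 2·D·dt), beaching against a land mask, Monte Carlo over start
   times, and a convex-hull uncertainty region from a perturbed-forcing
   particle ensemble.
2. **Oil fate** — pseudo-component first-order evaporation,
   dm_i/dt = −k_i·(1 + 0.045·U)·2^((SST−15)/10)·m_i, plus skimming,
   episodic in-situ burning and dispersant, mass-conserving to 1e−9.
3. **PM2.5 dispersion** — a single-layer Lagrangian model: emission rate =
   oil mass (µg) × conversion rate ÷ release duration, particles on the
   10-m wind with Gaussian turbulence, uniform mixing over 800 m, 24-hour
   average concentration fields.
4. **Health impacts** — log-linear exposure–response
   IR(c) = 100·(exp(β·c) − 1), β = ln(1 + slope/100)/10, population-weighted
   over cells ≥ 10 µg/m³, person-days of exposure, and Monte Carlo
   propagation of slope and conversion-rate uncertainty with
   sd = ln(CI_hi/CI_lo)/(2·qnorm(0.975)).
5. **Supply disruption** — port exposure percentiles, desalination capacity
   and population equivalents, fuel-import and food-aid series statistics,
   fuel price spikes, and fishery-yield loss under percentile thresholds.

All inputs — winds, currents, SST, salinity, population, ports, plants,
fishery yields, socio-economic series — are generated synthetically with the
statistical structure of the real products (seasonal mean circulation +
AR(1) perturbations; see the methods vignette in `vignettes/`).

## Worked example

```r
library(spillimpact)

## one call runs environment -> transport -> fate -> dispersion -> health
## -> supply impacts and writes CSV/GeoJSON outputs plus a manifest
m <- runPipeline(defaultRunConfig(seed = 1, out_dir = "spill-run"))

m$health[, c("scenario", "mean_IR", "IR_lo", "IR_hi", "person_days")]
#>                     scenario   mean_IR     IR_lo     IR_hi person_days
#> 1 summer, fast-release, leak  3.503632  2.151940  4.665239    2.979280
#> 2 winter, fast-release, leak  0.000000  0.000000  0.000000    0.000000
#> 3 summer, slow-release, leak  2.629170  1.859852  3.605922    3.760939
#> 4 winter, slow-release, leak  2.720468  1.592757  3.643870    1.075573
#> 5 summer, fast-release, fire 24.503019 22.228094 26.941342    3.828266
#> 6 winter, fast-release, fire  0.000000  0.000000  0.000000    0.000000
#> 7 summer, slow-release, fire 14.423056 13.233193 15.725162    9.942861
#> 8 winter, slow-release, fire 14.695952 13.252590 16.146285    2.164595
```

The table is the pipeline's central product: population-weighted average
increased risk (IR, %) of cardiovascular/respiratory hospitalisation with
95% uncertainty intervals, and person-days of exposure (millions) above
10 µg/m³, for the 2 seasons × fast/slow release × leak/fire scenario
matrix. Zero rows are real outcomes: in those winter scenarios the plume
blows west over open water and misses the population entirely.

Downstream estimators read the same run:

```r
subset(m$impacts$ports, week == "week2" & season == "summer")
#>                         name percentile reached exposed status season  week
#> summer week2.1 Hudaydah-like    97.8803    TRUE    TRUE     ok summer week2
#> ...
```

The key eastern aid port sits in the ~98th percentile of surface-oil
exposure two weeks into a summer spill — "directly impacted" under the
90th-percentile rule — which in turn drives the food-aid estimate
(`m$impacts$food`: 3.8 million people, 95% UI 2.4–5.3, from the port's 45%
food-aid share times the monthly people-targeted series). Winter spills
drift north instead and disrupt 310,000 m³/day of desalination capacity
versus 30,000 m³/day in summer (`m$impacts$desal`).

Individual stages are ordinary functions on S4 containers
(`EnvironmentFields`, `SurfaceConcentrationField`, `PM25Field`,
`FateEnsemble`, …) and can be used alone:

```r
spec <- gridSpec(12, 17, 41.5, 44.5, 0.25, "2020-06-01", "2020-06-29", 1)
env  <- generateEnvironment(spec, "summer", seed = 1)
oil  <- oilProperties()
fate <- runFate(oil, fateWeatherDraws(env, c(43.3, 15.15), n_mc = 1000, seed = 2))
budgetSeries(fate)[25, c("evaporated", "lo95_evaporated", "hi95_evaporated")]
#>    evaporated lo95_evaporated hi95_evaporated
#> 25  0.5283712       0.5149143       0.5437942
```

About 53% (95% UI 51–54%) of the oil evaporates within 24 hours under
summer conditions — the light components go to the atmosphere while the
heavy residue stays afloat.

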