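# Weathering mass budget: analytic limits, clean-up arithmetic, mass
# conservation and Monte Carlo summaries.

calmWeather <- function(h = 144, wind = 0, sst = 15)
  data.frame(wind_speed = rep(wind, h), sst = rep(sst, h))

test_that("inert oil never evaporates and starts fully floating", {
  oil <- oilProperties(components = data.frame(fraction = c(0.6, 0.4),
                                               k_h = c(0, 0)))
  b <- budgetSeries(runFateOnce(oil, calmWeather()))
  expect_identical(b$evaporated[1], 0)          # initial condition
  expect_true(all(b$evaporated == 0))
  expect_true(all(b$floating == 1))
})

test_that("single-component evaporation matches the analytic solution", {
  oil <- oilProperties(components = data.frame(fraction = 1, k_h = 0.05))
  w <- calmWeather(144, wind = 5, sst = 29)
  lambda <- 0.05 * evaporationModifier(5, 29)
  b <- budgetSeries(runFateOnce(oil, w))
  expect_lt(max(abs(b$evaporated - (1 - exp(-lambda * b$time_h)))), 1e-6)
})

test_that("the default skimmer removes 14 bbl/h for 144 h", {
  oil <- oilProperties()
  cfg <- cleanupConfig(burn_efficiency = 0, dispersant_fraction = 0)
  b <- budgetSeries(runFateOnce(oil, calmWeather(), cfg))
  skimmed_bbl <- b$skimmed[nrow(b)] * oil$total_mass_t / oil$density_t_per_bbl
  expect_equal(skimmed_bbl, 14 * 144, tolerance = 1e-9)
})

test_that("zero-efficiency clean-up reproduces the evaporation-only budget", {
  oil <- oilProperties()
  w <- calmWeather(144, wind = 5, sst = 29)
  cfg <- cleanupConfig(skimmer_efficiency = 0, burn_efficiency = 0,
                       dispersant_efficiency = 0)
  expect_equal(budgetSeries(runFateOnce(oil, w, cfg)),
               budgetSeries(runFateOnce(oil, w)), tolerance = 1e-12)
})

test_that("removals are capped when nothing is floating", {
  # oil that evaporates almost immediately: clean-up finds nothing to remove
  oil <- oilProperties(components = data.frame(fraction = 1, k_h = 5))
  b <- budgetSeries(runFateOnce(oil, calmWeather(48, 10, 30),
                                cleanupConfig(), horizon_h = 48))
  expect_true(all(rowSums(b[, -1]) - 1 < 1e-9))
  expect_true(all(b$floating >= -1e-12))
  expect_lt(b$skimmed[nrow(b)] + b$burned[nrow(b)] + b$dispersed[nrow(b)], 0.02)
})

test_that("compartments conserve mass and removals are monotone", {
  oil <- oilProperties()
  set.seed(8)
  w <- data.frame(wind_speed = runif(144, 0, 12), sst = runif(144, 25, 32))
  for (cfg in list(NULL, cleanupConfig())) {
    b <- budgetSeries(runFateOnce(oil, w, cfg))
    expect_true(all(abs(rowSums(b[, -1]) - 1) < 1e-9))
    for (cn in c("evaporated", "skimmed", "burned", "dispersed"))
      expect_true(all(diff(b[[cn]]) >= -1e-12))
    expect_true(all(diff(b$floating) <= 1e-12))
  }
})

test_that("clean-up never leaves more floating oil than weathering alone", {
  oil <- oilProperties()
  set.seed(9)
  w <- data.frame(wind_speed = runif(144, 0, 10), sst = runif(144, 26, 32))
  evap <- budgetSeries(runFateOnce(oil, w))
  clean <- budgetSeries(runFateOnce(oil, w, cleanupConfig()))
  expect_true(all(clean$floating <= evap$floating + 1e-12))
  # and at the defaults the two runs differ by under 5 percentage points
  expect_lt(abs(clean$floating[145] - evap$floating[145]), 0.05)
})

test_that("Monte Carlo summary collapses for zero-variance weather", {
  oil <- oilProperties()
  fe <- runFate(oil, calmWeather(144, 5, 29), n_mc = 5)
  s <- budgetSeries(fe)
  expect_equal(s$lo95_floating, s$floating, tolerance = 1e-12)
  expect_equal(s$hi95_evaporated, s$evaporated, tolerance = 1e-12)
})

test_that("ensemble means equal the brute-force average of stored draws", {
  oil <- oilProperties()
  set.seed(10)
  draws <- lapply(1:30, function(i)
    data.frame(wind_speed = runif(144, 0, 10), sst = runif(144, 26, 32)))
  fe <- runFate(oil, draws)
  expect_identical(nSimulations(fe), 30L)
  s <- budgetSeries(fe)
  expect_equal(s$floating, colMeans(fe@draws[, , "floating"]), tolerance = 1e-12)
  expect_equal(s$lo95_evaporated,
               apply(fe@draws[, , "evaporated"], 2,
                     function(x) unname(quantile(x, 0.025, type = 7))),
               tolerance = 1e-12)
})

test_that("fate contracts are enforced", {
  oil <- oilProperties()
  expect_error(runFateOnce(oil, calmWeather(200), horizon_h = 200), "144")
  expect_error(runFate(oil, calmWeather(), n_mc = 1), ">= 2")
  expect_error(oilProperties(components = data.frame(fraction = c(0.5, 0.4),
                                                     k_h = c(0, 0))),
               "sum to 1")
})
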