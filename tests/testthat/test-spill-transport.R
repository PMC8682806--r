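# Lagrangian transport kinematics, beaching, release schedule, particle
# accounting and the seasonality of the synthetic forcing.

test_that("advection displaces by (current + windage * wind) * dt", {
  # 0.5 m/s current east over 1 h: 1800 m
  p <- advectStep(43, 15, 0.5, 0, 0, 0, 0.03, 3600)
  expect_equal((p$lon - 43) * 111320 * cos(15 * pi / 180), 1800, tolerance = 1e-9)
  expect_equal(p$lat, 15)
  # 10 m/s wind north at 3% windage over 1 h: 1080 m
  p <- advectStep(43, 15, 0, 0, 0, 10, 0.03, 3600)
  expect_equal((p$lat - 15) * 111320, 1080, tolerance = 1e-9)
  expect_equal(p$lon, 43)
  # no forcing: identity
  p <- advectStep(43, 15, 0, 0, 0, 0, 0.03, 3600)
  expect_identical(c(p$lon, p$lat), c(43, 15))
})

test_that("diffusion is a zero-mean random walk with variance 2 D dt", {
  p <- diffuseStep(43, 15, 0, 600)
  expect_identical(c(p$lon, p$lat), c(43, 15))  # D = 0: no motion
  set.seed(1)
  a <- diffuseStep(43, 15, 10, 600)
  set.seed(1)
  b <- diffuseStep(43, 15, 10, 600)
  expect_identical(a, b)  # fixed seed: identical trajectory
  set.seed(2)
  n <- 20000
  p <- diffuseStep(rep(0, n), rep(0, n), 10, 600)
  dx <- p$lon * 111320
  expect_equal(stats::var(dx), 2 * 10 * 600, tolerance = 0.05)
  expect_lt(abs(mean(dx)), 3 * sqrt(12000 / n))
})

test_that("particles are released uniformly over the release window", {
  spec <- tinySpec(days = 3, lat = c(13, 17), lon = c(41, 45))
  env <- constantEnv(spec, current = c(0.3, 0))
  cfg <- trajectoryConfig(n_particles = 48, n_uncertainty = 0,
                          n_simulations = 1, horizon_days = 2,
                          release_hours = 24, windage = c(0.02, 0.02),
                          diffusivity = 0, seed = 3)
  res <- runSpillSimulation(env, c(42, 15), cfg)
  # first released travels farthest east; later releases strictly behind
  lon <- res$particles$lon
  expect_true(all(diff(lon) <= 1e-12))
  # last particle released within the 24-h window still moved >= horizon-24h
  expect_true(min(lon) > 42)
})

test_that("uniform eastward flow beaches every particle on the east coast", {
  spec <- tinySpec(days = 8, lat = c(13, 17), lon = c(41, 45))
  env <- constantEnv(spec, current = c(0.3, 0))
  mask <- channelLandMask(spec, 41.5, 43.5)
  cfg <- trajectoryConfig(n_particles = 30, n_uncertainty = 5,
                          n_simulations = 1, horizon_days = 7,
                          release_hours = 24, diffusivity = 0, seed = 4)
  res <- runSpillSimulation(env, c(42.6, 15), cfg, land_mask = mask)
  base <- res$particles[!res$particles$is_uncertainty, ]
  expect_true(all(base$status == "beached"))
  expect_true(all(base$lon > 43.4 & base$lon <= 43.5 + 1e-6))
  expect_error(runSpillSimulation(env, c(44.5, 15), cfg, land_mask = mask),
               "on land")
})

test_that("particle statuses partition the ensemble at the end of a run", {
  spec <- tinySpec(days = 8, lat = c(13, 17), lon = c(41, 45))
  env <- generateEnvironment(spec, "summer", seed = 2)
  mask <- channelLandMask(spec, 41.5, 43.5)
  cfg <- trajectoryConfig(n_particles = 40, n_uncertainty = 40,
                          n_simulations = 1, horizon_days = 7,
                          release_hours = 24, seed = 5)
  res <- runSpillSimulation(env, c(42.6, 15), cfg, land_mask = mask)
  expect_identical(nrow(res$particles), 80L)
  expect_true(all(res$particles$status %in%
                    c("floating", "beached", "out_of_domain")))
  expect_true(all(res$particles$value >= 0))
})

test_that("uncertainty particles outrun base particles under scaled forcing", {
  spec <- tinySpec(days = 4, lat = c(13, 17), lon = c(40, 46))
  env <- constantEnv(spec, current = c(0.2, 0), wind = c(3, 0))
  cfg <- trajectoryConfig(n_particles = 40, n_uncertainty = 40,
                          n_simulations = 1, horizon_days = 3,
                          release_hours = 0, diffusivity = 0, seed = 6)
  res <- runSpillSimulation(env, c(41, 15), cfg, unc_multiplier = 1.5)
  p <- res$particles
  expect_gt(mean(p$lon[p$is_uncertainty]), mean(p$lon[!p$is_uncertainty]))
})

test_that("synthetic seasons reproduce the qualitative drift directions", {
  spec <- gridSpec(12, 18, 41.5, 44.5, 0.25, "2020-01-01",
                   as.POSIXct("2020-01-01", tz = "UTC") + 10 * 86400, 1)
  mask <- channelLandMask(spec, 42, 43.5)
  src <- c(43.0, 15.0)
  run <- function(season, seed) {
    env <- generateEnvironment(spec, season, seed = seed)
    cfg <- trajectoryConfig(n_particles = 40, n_uncertainty = 0,
                            n_simulations = 4, horizon_days = 7,
                            release_hours = 24, seed = seed)
    runSpillEnsemble(env, src, cfg, mask)$mean_final
  }
  summer <- run("summer", 21)
  winter <- run("winter", 22)
  expect_gt(winter["lat"], src[2])         # winter: northward along the axis
  expect_lt(summer["lat"], src[2])         # summer: southward component
  expect_gt(summer["lon"], src[1])         # ... and eastward: southeast drift
})

test_that("trajectory configuration contracts are enforced", {
  expect_error(trajectoryConfig(windage = c(0.04, 0.01)), "windage")
  expect_error(trajectoryConfig(diffusivity = -1), "diffusivity")
  expect_error(trajectoryConfig(horizon_days = 1, release_hours = 168),
               "release")
  expect_error(trajectoryConfig(uncertainty_scale = c(0.5, 1)), "uncertainty")
})
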