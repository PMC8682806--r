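# End-to-end orchestration: environment -> spill transport -> oil fate ->
# atmospheric dispersion -> health impacts -> supply disruption, with
# per-stage seeds derived from one global seed and an output manifest with
# checksums so identical configurations give identical results.

#' Synthetic study-region asset layer
#'
#' Ports, desalination plants, fishery yield and socio-economic series for
#' the idealised two-coast channel domain: two key aid ports on the eastern
#' coast near the spill site (joint food-aid share 68%) plus a southern port
#' outside the channel mouth, desalination plants along both coasts (the
#' eastern country's plant capacities unknown, to exercise the
#' equal-division rule), a gridded fishery-yield layer over the water cells
#' split into a northern "Red Sea" and a southern "Gulf of Aden" region, and
#' monthly fuel-import, fuel-price and food-assistance series. All values
#' are synthetic but sized like the real region's.
#'
#' @param spec a [GridSpec-class] for the fishery grid
#' @param west_lon,east_lon channel water bounds (as in [channelLandMask()])
#' @return list: `assets` (an [assetLayer()]), `per_capita_use`,
#'   `country_capacity`, `monthly_fuel_imports`, `prices_t0`, `prices_t1`,
#'   `food_aid_shares`, `targeted_series`
#' @export
syntheticAssets <- function(spec, west_lon = 42.0, east_lon = 43.5) {
  # coastal assets sit exactly on the waterline, where drifting oil beaches
  coast_e <- east_lon
  coast_w <- west_lon
  ports <- data.frame(
    name = c("Hudaydah-like", "Salif-like", "Aden-like"),
    lon = c(coast_e, coast_e, coast_e),
    lat = c(14.8, 15.3, 12.4),
    food_aid_share = c(0.45, 0.23, 0.32),
    monthly_fuel_tons = c(120000, 80000, 60000))
  desalination <- data.frame(
    name = c("east-plant-1", "east-plant-2", "east-plant-3",
             "west-plant-1", "north-plant-1"),
    lon = c(coast_e, coast_e, coast_e, coast_w, coast_e),
    lat = c(14.6, 15.5, 16.2, 15.8, 16.6),
    capacity_m3_per_day = c(NA, NA, NA, 120000, 250000),
    country = c("east", "east", "east", "west", "north"))
  lats <- latCentres(spec); lons <- lonCentres(spec)
  # the eastern country's fishing grounds: the eastern half of the channel
  water <- expand.grid(lat = lats, lon = lons)
  water <- water[water$lon >= (west_lon + east_lon) / 2 & water$lon <= east_lon, ]
  set.seed(20160101)  # fixed: the yield layer is a static input, not a draw
  water$yield_tons <- round(stats::runif(nrow(water), 50, 500))
  water$region <- ifelse(water$lat >= 13, "Red Sea", "Gulf of Aden")
  assets <- assetLayer(ports, desalination, water)
  list(assets = assets,
       per_capita_use = c(east = 0.02, west = 0.05, north = 0.1),
       country_capacity = c(east = 90000),
       monthly_fuel_imports = c(180000, 188000, 196000, 212000, 248000),
       prices_t0 = c(diesel = 240, petrol = 250, gas = 260),
       prices_t1 = c(diesel = 413, petrol = 430, gas = 447),
       food_aid_shares = c("Hudaydah-like" = 0.45, "Salif-like" = 0.23,
                           "Aden-like" = 0.32),
       targeted_series = 1e6 * c(5.2, 6.1, 7.0, 7.7, 8.2, 8.7, 9.3, 9.9, 10.9, 12.0))
}

#' Default pipeline configuration
#'
#' A complete run configuration at desk scale: the simulation counts are
#' reduced from operational scale (thousands of simulations) to sizes a
#' single CPU covers in minutes, while keeping every structural element
#' (seasonal ensembles, weekly fields, 8-scenario health table, weekly
#' fishery series). Any element can be overridden via `modifyList()`-style
#' replacement in `runPipeline()`.
#'
#' @param seed global seed; stage seeds derive from it via [stageSeed()]
#' @param out_dir output directory
#' @return nested configuration list
#' @export
defaultRunConfig <- function(seed = 1, out_dir = tempfile("spillrun")) {
  list(
    seed = seed, out_dir = out_dir,
    domain = list(lat_min = 12, lat_max = 17, lon_min = 41.5, lon_max = 44.5,
                  cell_size = 0.25, days = 28, west_lon = 42.0, east_lon = 43.5,
                  # the stricken tanker is moored a few nautical miles off
                  # the eastern coast, between the two key aid ports
                  source = c(43.3, 15.15)),
    seasons = c("summer", "winter"),
    # desk-scale ensembles are sparser than operational ones, so the
    # pipeline grids at the coarser ~1.1 km (2-decimal) resolution variant
    transport = list(n_particles = 150, n_uncertainty = 150,
                     n_simulations = 20, horizon_days = 21,
                     release_hours = 168, decimals = 2),
    fate = list(n_mc = 200, horizon_h = 144),
    dispersion = list(n_particles = 500, run_hours = 96, n_starts = 4),
    health = list(n_draws = 400, risk_preset = "burnett-style"),
    population = list(total = 8e6,
                      hotspots = list(
                        list(lon = 43.7, lat = 14.8, weight = 3, sigma = 0.4),
                        list(lon = 44.2, lat = 15.4, weight = 2, sigma = 0.5),
                        list(lon = 43.8, lat = 13.6, weight = 1, sigma = 0.4))))
}

#' Read a run configuration from a YAML file
#'
#' Values in the file override [defaultRunConfig()] recursively, so a config
#' file needs to name only what it changes (e.g. `seed`, `out_dir`,
#' `transport: {n_simulations: 100}`).
#'
#' @param path YAML file
#' @return configuration list for [runPipeline()]
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    contractStop("reading YAML configs requires the 'yaml' package")
  if (!file.exists(path)) contractStop("missing input path(s): ", path)
  utils::modifyList(defaultRunConfig(), yaml::read_yaml(path))
}

#' Run the full assessment pipeline
#'
#' Executes environment generation, spill-trajectory ensembles (per season,
#' with weekly concentration fields and the convex uncertainty region), oil
#' fate with and without clean-up, PM2.5 dispersion and the 8-scenario
#' (2 seasons x fast/slow release x leak/fire) health table, and the supply
#' disruption estimators, writing CSV/GeoJSON outputs plus a JSON manifest
#' with the seed and per-file MD5 checksums. Identical configuration and
#' seed give identical checksums.
#'
#' @param config a configuration list from [defaultRunConfig()]
#' @return the manifest, invisibly (list: `seed`, `stage_seeds`, `files`,
#'   `checksums`, `summary`)
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  t_all <- Sys.time()
  # pre-flight: every externally referenced path must exist before any stage runs
  if (!is.null(config$paths)) {
    missing <- Filter(function(p) !file.exists(p), unlist(config$paths))
    if (length(missing))
      contractStop("missing input path(s): ", paste(missing, collapse = ", "))
  }
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", file = log_path, append = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    logline("stage %-12s %.1f s", name, as.numeric(Sys.time() - t0, units = "secs"))
    r
  }
  dm <- config$domain
  seeds <- vapply(c("environment", "transport", "fate", "dispersion",
                    "health", "impacts"),
                  function(s) stageSeed(config$seed, s), integer(1))

  # --- environment -------------------------------------------------------
  spec <- gridSpec(dm$lat_min, dm$lat_max, dm$lon_min, dm$lon_max, dm$cell_size,
                   "2020-01-01 00:00:00",
                   as.POSIXct("2020-01-01 00:00:00", tz = "UTC") + dm$days * 86400,
                   1)
  mask <- channelLandMask(spec, dm$west_lon, dm$east_lon)
  envs <- stage("environment", lapply(stats::setNames(config$seasons, config$seasons),
    function(sn) {
      if (!is.null(config$paths$environment[[sn]]))
        readEnvironment(config$paths$environment[[sn]])
      else generateEnvironment(spec, sn, seed = seeds["environment"] +
                                 match(sn, config$seasons))
    }))
  syn <- syntheticAssets(spec, dm$west_lon, dm$east_lon)
  if (!is.null(config$paths$assets)) syn$assets <- readAssets(config$paths$assets)
  pop <- generatePopulation(spec, config$population$total,
                            config$population$hotspots,
                            seed = seeds["environment"], land_mask = mask)

  files <- character()
  put <- function(name) { files[[length(files) + 1]] <<- file.path(out, name); file.path(out, name) }

  # --- transport ---------------------------------------------------------
  tc <- config$transport
  transport <- stage("transport", lapply(envs, function(env) {
    cfg <- trajectoryConfig(n_particles = tc$n_particles,
                            n_uncertainty = tc$n_uncertainty,
                            n_simulations = tc$n_simulations,
                            horizon_days = tc$horizon_days,
                            release_hours = tc$release_hours,
                            decimals = tc$decimals,
                            seed = seeds["transport"])
    runSpillEnsemble(env, dm$source, cfg, mask)
  }))
  for (sn in names(transport)) {
    for (wk in names(transport[[sn]]$fields_by_week))
      writeConcentrationCSV(transport[[sn]]$fields_by_week[[wk]],
                            put(sprintf("concentration_%s_%s.csv", sn, wk)))
    if (!is.null(transport[[sn]]$region))
      writeRegionGeoJSON(transport[[sn]]$region,
                         put(sprintf("uncertainty_region_%s.geojson", sn)))
  }

  # --- oil fate ----------------------------------------------------------
  oil <- oilProperties()
  fate <- stage("fate", {
    weather <- fateWeatherDraws(envs[[1]], dm$source, config$fate$horizon_h,
                                config$fate$n_mc, seeds["fate"])
    list(evap_only = runFate(oil, weather, NULL, config$fate$horizon_h),
         cleanup = runFate(oil, weather, cleanupConfig(), config$fate$horizon_h))
  })
  utils::write.csv(budgetSeries(fate$evap_only), put("fate_evaporation_only.csv"),
                   row.names = FALSE)
  utils::write.csv(budgetSeries(fate$cleanup), put("fate_cleanup.csv"),
                   row.names = FALSE)

  # --- dispersion + health ----------------------------------------------
  dp <- config$dispersion
  scen_grid <- expand.grid(season = config$seasons, release = c(24, 72),
                           mode = c("leak", "fire"), stringsAsFactors = FALSE)
  health <- stage("health", {
    rows <- vector("list", nrow(scen_grid))
    for (i in seq_len(nrow(scen_grid))) {
      sc <- emissionScenario(season = scen_grid$season[i],
                             release_hours = scen_grid$release[i],
                             mode = scen_grid$mode[i], source = dm$source)
      pm <- disperse(sc, envs[[scen_grid$season[i]]],
                     n_particles = dp$n_particles, run_hours = dp$run_hours,
                     n_starts = dp$n_starts,
                     seed = seeds["dispersion"] + i)
      rows[[i]] <- propagateUncertainty(pm, pop,
        riskFunction(config$health$risk_preset),
        monteCarloConfig(n_draws = config$health$n_draws,
                         seed = seeds["health"] + i,
                         conversion_rate_sd = sc$conversion_sd))
    }
    do.call(rbind, rows)
  })
  utils::write.csv(health, put("health_table.csv"), row.names = FALSE)

  # --- supply impacts ----------------------------------------------------
  impacts <- stage("impacts", {
    rows <- list(); fl_rows <- list()
    cumul <- lapply(transport, function(tr) accumulateFields(tr$fields_by_week))
    for (sn in names(transport)) {
      for (wk in names(transport[[sn]]$fields_by_week)) {
        fld <- cumul[[sn]][[wk]]
        pct <- percentileTransform(fld)
        pe <- portExposure(pct, syn$assets$ports, radius_deg = 0.05)
        pe$season <- sn; pe$week <- wk
        rows[[paste(sn, wk)]] <- pe
        for (th in c("none", "p10", "p20")) {
          fl <- fisheryLoss(fld, syn$assets$fishery, "Red Sea", th)
          fl_rows[[paste(sn, wk, th)]] <- data.frame(
            season = sn, week = wk, threshold = th,
            threatened_fraction = fl$threatened_fraction)
        }
      }
    }
    port_tab <- do.call(rbind, rows)
    fish_tab <- do.call(rbind, fl_rows)
    week3 <- lapply(cumul, function(cf) cf[[length(cf)]])
    desal <- lapply(week3, function(fld)
      desalDisruption(fld, syn$assets$desalination, syn$per_capita_use,
                      syn$country_capacity, radius_deg = 0.05))
    # closure criterion: oil reaching the port by week 2 in either season
    wk2 <- port_tab[port_tab$week == "week2", ]
    disrupted_ports <- unique(wk2$name[wk2$reached])
    fuel <- fuelDisruption(syn$monthly_fuel_imports)
    food <- foodAidDisruption(syn$food_aid_shares, syn$targeted_series,
                              disrupted_ports)
    list(ports = port_tab, fishery = fish_tab, desal = desal, fuel = fuel,
         food = food, price_spike = priceSpike(syn$prices_t0, syn$prices_t1))
  })
  utils::write.csv(impacts$ports, put("port_exposure.csv"), row.names = FALSE)
  utils::write.csv(impacts$fishery, put("fishery_loss.csv"), row.names = FALSE)
  desal_tab <- do.call(rbind, lapply(names(impacts$desal), function(sn)
    data.frame(season = sn,
               total_disrupted_m3_day = impacts$desal[[sn]]$total_disrupted_m3_day,
               population_equivalent = impacts$desal[[sn]]$population_equivalent)))
  utils::write.csv(desal_tab, put("desalination_impact.csv"), row.names = FALSE)
  supply_tab <- data.frame(
    quantity = c("fuel_disrupted_mean_t", "fuel_disrupted_lo95_t",
                 "fuel_disrupted_hi95_t", "food_aid_mean_persons",
                 "food_aid_lo95_persons", "food_aid_hi95_persons",
                 "price_spike_pct"),
    value = c(impacts$fuel$mean, impacts$fuel$lo95, impacts$fuel$hi95,
              impacts$food$mean, impacts$food$lo95, impacts$food$hi95,
              impacts$price_spike))
  utils::write.csv(supply_tab, put("supply_impacts.csv"), row.names = FALSE)

  files <- unlist(files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("spillimpact")),
    seed = config$seed, stage_seeds = as.list(seeds),
    files = basename(files),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)), basename(files))),
    runtime_s = as.numeric(Sys.time() - t_all, units = "secs"))
  writeLines(jsonlite::toJSON(manifest[names(manifest) != "runtime_s"],
                              auto_unbox = TRUE, digits = NA),
             file.path(out, "manifest.json"))
  logline("total %.1f s", manifest$runtime_s)
  invisible(c(manifest, list(
    health = health, transport = transport, fate = fate, impacts = impacts,
    population = pop, environments = envs, assets = syn)))
}
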