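# Small fixtures shared across tests; everything is built in code.

tinySpec <- function(days = 2, cell = 0.25, lat = c(14, 16), lon = c(42, 44),
                     t_step_h = 1) {
  gridSpec(lat[1], lat[2], lon[1], lon[2], cell,
           "2020-06-01 00:00:00",
           as.POSIXct("2020-06-01 00:00:00", tz = "UTC") + days * 86400,
           t_step_h)
}

# constant (deterministic) forcing via the generator with zero variance
constantEnv <- function(spec, current = c(0, 0), wind = c(0, 0), sst = 29,
                        salinity = 40, season = "summer") {
  generateEnvironment(spec, season, params = list(
    mean_current = current, mean_wind = wind, sd_current = 0, sd_wind = 0,
    ar1 = 0, mean_sst = sst, sd_sst = 0, mean_salinity = salinity,
    sd_salinity = 0, smooth_cells = 0), seed = 1)
}

# sparse concentration field from a (lat, lon, value) data.frame
makeField <- function(cells, decimals = 2, n_simulations = 1,
                      units = "thickness_m") {
  cells <- cells[order(cells$lat, cells$lon), ]
  rownames(cells) <- NULL
  new("SurfaceConcentrationField", cells = cells, decimals = decimals,
      n_simulations = n_simulations, units = units)
}

# PM2.5 field with given value matrix (and optional daily stack)
makePM <- function(spec, values, daily = NULL, release_hours = 24,
                   conversion_rate = 0.008, season = "summer", mode = "leak") {
  if (is.null(daily)) {
    nd <- ceiling(release_hours / 24)
    daily <- array(rep(values, each = nd), c(nd, nrow(values), ncol(values)))
  }
  new("PM25Field", grid = spec, values = values, daily = daily,
      scenario = list(season = season, release_hours = release_hours,
                      mode = mode),
      n_ensemble = 1, conversion_rate = conversion_rate,
      audit = list(emitted_ug = 0, in_domain_ug = 0, out_of_domain_ug = 0))
}

uniformPop <- function(spec, per_cell = 100) {
  d <- gridDim(spec)
  new("PopulationGrid", grid = spec,
      count = matrix(per_cell, d[2], d[3]))
}
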