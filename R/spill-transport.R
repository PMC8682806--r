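# Lagrangian surface-oil transport: windage + current advection with a
# random-walk diffusion closure, forward-Euler stepping, beaching against a
# land mask, and Monte Carlo ensembles over release start times.

#' Trajectory ensemble configuration
#'
#' @param n_particles trajectory particles per simulation
#' @param n_uncertainty uncertainty particles per simulation (perturbed
#'   forcing); defaults to `n_particles`
#' @param n_simulations Monte Carlo simulations (start times vary)
#' @param horizon_days simulation length per spill
#' @param release_hours spill (release) duration; particles are released
#'   uniformly over this window. 168 h is a 7-day spill; 24 h is the
#'   fast-release variant
#' @param windage interval `c(lo, hi)`: each particle's wind drift factor is
#'   drawn uniformly from it at release and kept for life
#' @param diffusivity horizontal diffusivity, m^2/s
#' @param dt_min integration step, minutes (forward Euler)
#' @param decimals coordinate rounding for concentration gridding; 3 is
#'   roughly a 100 m x 100 m cell, 2 roughly 1.1 km
#' @param uncertainty_scale interval for the per-simulation forcing
#'   multiplier applied to currents and windage of uncertainty particles
#'   (their diffusivity is doubled); the perturbed envelope stands in for an
#'   extreme-weather parameterisation
#' @param total_volume_bbl spilled volume (barrels) carried by the particles
#' @param seed integer seed
#' @return validated list of class `"trajectoryConfig"`
#' @export
trajectoryConfig <- function(n_particles = 1000, n_uncertainty = n_particles,
                             n_simulations = 1000, horizon_days = 21,
                             release_hours = 168, windage = c(0.01, 0.04),
                             diffusivity = 10, dt_min = 15, decimals = 3,
                             uncertainty_scale = c(1.0, 1.5),
                             total_volume_bbl = 1.1e6, seed = 1) {
  if (n_particles < 1) contractStop("n_particles must be >= 1")
  if (windage[1] < 0 || windage[2] < windage[1] || windage[2] >= 1)
    contractStop("windage interval must satisfy 0 <= lo <= hi < 1")
  if (diffusivity < 0) contractStop("diffusivity must be >= 0")
  if (dt_min <= 0) contractStop("dt_min must be > 0")
  if (horizon_days * 24 < release_hours)
    contractStop("horizon must be at least the release duration")
  if (any(uncertainty_scale < 1)) contractStop("uncertainty_scale must be >= 1")
  structure(list(n_particles = n_particles, n_uncertainty = n_uncertainty,
                 n_simulations = n_simulations, horizon_days = horizon_days,
                 release_hours = release_hours, windage = windage,
                 diffusivity = diffusivity, dt_min = dt_min,
                 decimals = decimals, uncertainty_scale = uncertainty_scale,
                 total_volume_bbl = total_volume_bbl, seed = seed),
            class = "trajectoryConfig")
}

#' Advect particle positions one step
#'
#' Deterministic displacement `(current + windage * wind) * dt`, converted to
#' degrees using the local metres-per-degree at each particle's latitude.
#' Vectorised over particles.
#'
#' @param lon,lat positions, degrees
#' @param current_u,current_v surface current, m/s
#' @param wind_u,wind_v 10-m wind, m/s
#' @param windage wind drift fraction (scalar or per particle)
#' @param dt_s step length, seconds
#' @return list with updated `lon`, `lat`
#' @examples
#' advectStep(43, 15, 0.5, 0, 0, 0, 0.03, 3600) # 1800 m east
#' @export
advectStep <- function(lon, lat, current_u, current_v, wind_u, wind_v,
                       windage, dt_s) {
  dx <- (current_u + windage * wind_u) * dt_s
  dy <- (current_v + windage * wind_v) * dt_s
  list(lon = lon + dx / metresPerDegLon(lat),
       lat = lat + dy / EARTH_M_PER_DEG_LAT)
}

#' Diffuse particle positions one step
#'
#' Independent zero-mean Gaussian jumps in x and y with variance
#' `2 * diffusivity * dt` per axis (random-walk closure of the Lagrangian
#' model). Uses the current RNG state; seed outside for reproducibility.
#'
#' @param lon,lat positions, degrees
#' @param diffusivity horizontal diffusivity, m^2/s (scalar or per particle)
#' @param dt_s step length, seconds
#' @return list with updated `lon`, `lat`
#' @export
diffuseStep <- function(lon, lat, diffusivity, dt_s) {
  n <- length(lon)
  sd_m <- sqrt(2 * diffusivity * dt_s)
  list(lon = lon + stats::rnorm(n, 0, sd_m) / metresPerDegLon(lat),
       lat = lat + stats::rnorm(n, 0, sd_m) / EARTH_M_PER_DEG_LAT)
}

# One simulated spill: base + uncertainty particles stepped jointly.
# Returns week snapshots (floating + beached particles), final state, and
# final uncertainty-particle locations.
#' Run a single spill simulation
#'
#' Releases particles uniformly over the release window at the source and
#' steps them with advection then diffusion until the horizon. Particles
#' crossing the land mask are beached at their last water position and never
#' move again; particles leaving the field domain are frozen with status
#' `out_of_domain`. Uncertainty particles see currents and windage scaled by
#' `unc_multiplier` and doubled diffusivity.
#'
#' @param fields an [EnvironmentFields-class]
#' @param source `c(lon, lat)` of the spill site (must be in water)
#' @param config a [trajectoryConfig()]
#' @param land_mask optional logical `(lat, lon)` matrix, `TRUE` = land
#' @param t0_index index into the field's time axis at which the spill starts
#' @param unc_multiplier forcing multiplier for uncertainty particles
#' @param sim_seed integer seed for this simulation
#' @return list with `particles` (data.frame: lon, lat, value, status,
#'   is_uncertainty), `snapshots` (named list of week-end data.frames of
#'   non-lost particles), `uncertainty_points` (matrix lon/lat)
#' @export
runSpillSimulation <- function(fields, source, config, land_mask = NULL,
                               t0_index = 1L, unc_multiplier = 1.0,
                               sim_seed = config$seed) {
  stopifnot(is(fields, "EnvironmentFields"), inherits(config, "trajectoryConfig"))
  spec <- fields@grid
  if (onLand(land_mask, spec, source[1], source[2]))
    contractStop("spill source lies on land")
  set.seed(as.integer(sim_seed) %% 2147483647L)

  n_base <- config$n_particles
  n_unc <- config$n_uncertainty
  n <- n_base + n_unc
  is_unc <- c(rep(FALSE, n_base), rep(TRUE, n_unc))
  dt_s <- config$dt_min * 60
  n_steps <- ceiling(config$horizon_days * 24 * 3600 / dt_s)
  release_step <- function(k) 1L + floor((seq_len(k) - 1L) / k *
                                           config$release_hours * 3600 / dt_s)
  rel <- c(release_step(n_base), release_step(n_unc))
  windage <- stats::runif(n, config$windage[1], config$windage[2])
  windage[is_unc] <- windage[is_unc] * unc_multiplier
  diffusivity <- ifelse(is_unc, 2 * config$diffusivity, config$diffusivity)
  cur_mult <- ifelse(is_unc, unc_multiplier, 1)

  # per-particle surface value: equal thickness share on a decimals-rounded cell
  cell_deg <- 10^(-config$decimals)
  cell_area_m2 <- (cell_deg * EARTH_M_PER_DEG_LAT) *
    (cell_deg * metresPerDegLon(source[2]))
  vol_m3 <- config$total_volume_bbl * 0.158987
  value <- vol_m3 / n_base / cell_area_m2

  lon <- rep(source[1], n); lat <- rep(source[2], n)
  status <- rep(NA_integer_, n)  # NA = unreleased; 0 floating, 1 beached, 2 lost
  t_step_s <- spec@t_step_h * 3600
  week_steps <- round(7 * 24 * 3600 / dt_s) * seq_len(min(3, config$horizon_days %/% 7))
  snapshots <- list()

  for (k in seq_len(n_steps)) {
    status[is.na(status) & rel <= k] <- 0L
    act <- which(!is.na(status) & status == 0L)
    if (length(act)) {
      t_index <- t0_index + as.integer(round((k - 1) * dt_s / t_step_s))
      cu <- envSample(fields, "current_u", lon[act], lat[act], t_index) * cur_mult[act]
      cv <- envSample(fields, "current_v", lon[act], lat[act], t_index) * cur_mult[act]
      wu <- envSample(fields, "wind_u", lon[act], lat[act], t_index)
      wv <- envSample(fields, "wind_v", lon[act], lat[act], t_index)
      lost <- is.na(cu)
      if (any(lost)) status[act[lost]] <- 2L
      mv <- act[!lost]
      if (length(mv)) {
        p <- advectStep(lon[mv], lat[mv], cu[!lost], cv[!lost], wu[!lost],
                        wv[!lost], windage[mv], dt_s)
        p <- diffuseStep(p$lon, p$lat, diffusivity[mv], dt_s)
        beach <- onLand(land_mask, spec, p$lon, p$lat)
        # beached particles are anchored at their last water position
        out <- p$lon < spec@lon_min | p$lon > spec@lon_max |
          p$lat < spec@lat_min | p$lat > spec@lat_max
        keep <- !beach & !out
        lon[mv[keep]] <- p$lon[keep]; lat[mv[keep]] <- p$lat[keep]
        status[mv[beach]] <- 1L
        status[mv[out & !beach]] <- 2L
      }
    }
    if (k %in% week_steps) {
      wk <- which(k == week_steps)
      sel <- !is.na(status) & status %in% c(0L, 1L) & !is_unc
      snapshots[[paste0("week", wk)]] <- data.frame(
        lon = lon[sel], lat = lat[sel], value = rep(value, sum(sel)))
    }
  }
  status[is.na(status)] <- 0L
  unc_sel <- is_unc & status %in% c(0L, 1L)
  list(particles = data.frame(lon = lon, lat = lat, value = value,
                              status = c("floating", "beached", "out_of_domain")[status + 1L],
                              is_uncertainty = is_unc),
       snapshots = snapshots,
       uncertainty_points = cbind(lon = lon[unc_sel], lat = lat[unc_sel]))
}

#' Run a Monte Carlo spill ensemble
#'
#' Repeats [runSpillSimulation()] over `n_simulations` start times sampled
#' uniformly from the feasible range of the field's time axis (varying date
#' and time of day), draws a per-simulation uncertainty-forcing multiplier,
#' grids the weekly snapshots into ensemble-mean concentration fields and
#' builds the convex uncertainty region from all uncertainty particles of
#' all simulations.
#'
#' @inheritParams runSpillSimulation
#' @return list with `fields_by_week` (named list of
#'   [SurfaceConcentrationField-class]), `region` (an
#'   [UncertaintyRegion-class]), `uncertainty_points`, `final_status` (counts),
#'   `mean_final` (ensemble-mean final lon/lat of base particles)
#' @export
runSpillEnsemble <- function(fields, source, config, land_mask = NULL) {
  stopifnot(inherits(config, "trajectoryConfig"))
  spec <- fields@grid
  set.seed(as.integer(config$seed) %% 2147483647L)
  nt <- gridDim(spec)[1]
  horizon_steps <- config$horizon_days * 24 / spec@t_step_h
  t0_max <- max(1L, nt - as.integer(horizon_steps))
  t0 <- sample.int(t0_max, config$n_simulations, replace = TRUE)
  umult <- stats::runif(config$n_simulations,
                        config$uncertainty_scale[1], config$uncertainty_scale[2])

  snaps <- list(); unc_pts <- vector("list", config$n_simulations)
  status_tab <- c(floating = 0, beached = 0, out_of_domain = 0)
  fin_lon <- fin_lat <- numeric(0)
  for (i in seq_len(config$n_simulations)) {
    res <- runSpillSimulation(fields, source, config, land_mask,
                              t0_index = t0[i], unc_multiplier = umult[i],
                              sim_seed = stageSeed(config$seed, paste0("sim", i)))
    for (wk in names(res$snapshots)) snaps[[wk]][[i]] <- res$snapshots[[wk]]
    unc_pts[[i]] <- res$uncertainty_points
    base <- res$particles[!res$particles$is_uncertainty, ]
    tb <- table(base$status)
    status_tab[names(tb)] <- status_tab[names(tb)] + as.numeric(tb)
    fin_lon <- c(fin_lon, mean(base$lon)); fin_lat <- c(fin_lat, mean(base$lat))
  }
  fields_by_week <- lapply(snaps, gridConcentration, decimals = config$decimals)
  pts <- do.call(rbind, unc_pts)
  region <- if (!is.null(pts) && nrow(pts) >= 3) tryCatch(
    uncertaintyRegion(pts), error = function(e) NULL) else NULL
  list(fields_by_week = fields_by_week, region = region,
       uncertainty_points = pts, final_status = status_tab,
       mean_final = c(lon = mean(fin_lon), lat = mean(fin_lat)))
}
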