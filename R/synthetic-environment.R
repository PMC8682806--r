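# Synthetic environmental forcing: seasonal mean circulation plus AR(1)
# stochastic perturbations, spatially smoothed. Emulates the statistical
# structure of hourly reanalysis winds and ocean-model surface currents well
# enough to exercise transport, weathering and dispersion, without any
# external data.

#' Seasonal variability parameter sets
#'
#' Default mean circulation and perturbation parameters per season for an
#' idealised Red-Sea-like channel (axis running roughly NNW-SSE). The summer
#' mean flow points southeast along the axis and the winter mean flow points
#' north, reproducing the qualitative seasonal reversal of the region's
#' surface circulation; spring and autumn are weak transitional flows.
#'
#' Fields: `mean_current`, `mean_wind` (u, v in m/s), `sd_current`, `sd_wind`
#' (perturbation standard deviations), `ar1` (hourly lag-1 autocorrelation),
#' `mean_sst`/`sd_sst` (deg C), `mean_salinity`/`sd_salinity` (PSU),
#' `smooth_cells` (Gaussian spatial smoothing radius in cells).
#'
#' @param season `"summer"`, `"winter"`, `"spring"` or `"autumn"`
#' @return named list of variability parameters
#' @export
seasonParams <- function(season = c("summer", "winter", "spring", "autumn")) {
  season <- match.arg(season)
  base <- list(
    sd_current = 0.08, sd_wind = 2.0, ar1 = 0.9,
    sd_sst = 0.5, sd_salinity = 0.2, smooth_cells = 2
  )
  # the channel axis runs roughly N-S: seasonal mean flow is along-axis
  # (southeast-ward in summer, northward in winter) with only a weak
  # cross-channel component, as in the region's monsoon-driven circulation
  seasonal <- switch(season,
    summer = list(mean_current = c(0.04, -0.13), mean_wind = c(1.0, -3.2),
                  mean_sst = 31, mean_salinity = 38.5),
    winter = list(mean_current = c(0.02, 0.13), mean_wind = c(0.8, 3.2),
                  mean_sst = 27, mean_salinity = 39.5),
    spring = list(mean_current = c(0.02, 0.05), mean_wind = c(0.8, 1.5),
                  mean_sst = 29, mean_salinity = 39),
    autumn = list(mean_current = c(0.03, -0.05), mean_wind = c(1.0, -1.5),
                  mean_sst = 30, mean_salinity = 39))
  c(seasonal, base, list(season = season))
}

# Gaussian spatial smoothing of one (lat, lon) slice, kernel normalised so
# that white-noise input keeps unit variance (sum of squared weights = 1).
smoothSlice <- function(m, radius) {
  if (radius <= 0) return(m)
  half <- ceiling(2 * radius)
  w <- exp(-(seq(-half, half))^2 / (2 * radius^2))
  w <- w / sqrt(sum(w^2))
  pad <- function(v, k) c(rep(v[1], k), v, rep(v[length(v)], k))
  conv1 <- function(v) {
    vp <- pad(v, half)
    stats::filter(vp, w, sides = 2)[(half + 1):(half + length(v))]
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

# AR(1)-in-time, spatially smoothed Gaussian perturbation array (time,lat,lon)
# with marginal sd ~= sd and lag-1 autocorrelation phi.
arPerturbation <- function(nt, nlat, nlon, sd, phi, radius) {
  out <- array(0, dim = c(nt, nlat, nlon))
  if (sd == 0 || nt == 0) return(out)
  innov_sd <- sqrt(1 - phi^2)
  prev <- smoothSlice(matrix(stats::rnorm(nlat * nlon), nlat, nlon), radius)
  out[1, , ] <- prev
  if (nt > 1) for (t in 2:nt) {
    e <- smoothSlice(matrix(stats::rnorm(nlat * nlon), nlat, nlon), radius)
    prev <- phi * prev + innov_sd * e
    out[t, , ] <- prev
  }
  out * sd
}

# Rescale vector fields whose speed exceeds the cap.
capSpeed <- function(u, v, cap) {
  spd <- sqrt(u^2 + v^2)
  f <- ifelse(spd > cap, cap / spd, 1)
  list(u = u * f, v = v * f)
}

#' Generate synthetic environmental forcing fields
#'
#' Draws wind, current, SST and salinity on a regular grid as seasonal mean
#' plus first-order autoregressive (AR(1)) perturbations in time, spatially
#' smoothed with an isotropic Gaussian kernel. Identical `spec`, `params` and
#' `seed` give bit-identical output. Current speeds are capped at 3 m/s and
#' wind speeds at 40 m/s.
#'
#' @param spec a [GridSpec-class]
#' @param season season label; used to pick defaults via [seasonParams()]
#'   when `params` is `NULL`
#' @param params variability parameters (see [seasonParams()]); must contain
#'   finite values and `ar1` in `[0, 1)`
#' @param seed integer seed
#' @return an [EnvironmentFields-class] object
#' @examples
#' spec <- gridSpec(12, 17, 41, 44, 0.25, "2020-06-01", "2020-06-05", 1)
#' env <- generateEnvironment(spec, "summer", seed = 1)
#' @export
generateEnvironment <- function(spec, season = "summer", params = NULL, seed = 1) {
  stopifnot(is(spec, "GridSpec"))
  if (is.null(params)) params <- seasonParams(season)
  num <- unlist(params[c("mean_current", "mean_wind", "sd_current", "sd_wind",
                         "ar1", "mean_sst", "sd_sst", "mean_salinity",
                         "sd_salinity", "smooth_cells")])
  if (any(!is.finite(num))) contractStop("non-finite variability parameters")
  if (params$ar1 < 0 || params$ar1 >= 1)
    contractStop("temporal autocorrelation must be in [0, 1)")

  d <- gridDim(spec)
  set.seed(as.integer(seed) %% 2147483647L)
  gen <- function(mean, sd) mean + arPerturbation(d[1], d[2], d[3], sd,
                                                  params$ar1, params$smooth_cells)
  cur <- capSpeed(gen(params$mean_current[1], params$sd_current),
                  gen(params$mean_current[2], params$sd_current), 3)
  wnd <- capSpeed(gen(params$mean_wind[1], params$sd_wind),
                  gen(params$mean_wind[2], params$sd_wind), 40)
  sst <- gen(params$mean_sst, params$sd_sst)
  sal <- pmax(gen(params$mean_salinity, params$sd_salinity), 0)

  new("EnvironmentFields", grid = spec,
      wind_u = wnd$u, wind_v = wnd$v,
      current_u = cur$u, current_v = cur$v,
      sst = sst, salinity = sal, season = season)
}

#' Idealised two-coast channel land mask
#'
#' A rasterised north-south sea channel: cells with longitude centre outside
#' `[west_lon, east_lon]` are land. This exercises beaching and coastal asset
#' exposure without real coastline data.
#'
#' @param spec a [GridSpec-class]
#' @param west_lon,east_lon channel water bounds in degrees longitude
#' @return logical matrix `(lat, lon)`, `TRUE` = land
#' @export
channelLandMask <- function(spec, west_lon, east_lon) {
  lons <- lonCentres(spec)
  lats <- latCentres(spec)
  matrix(rep(lons < west_lon | lons > east_lon, each = length(lats)),
         nrow = length(lats))
}

#' Generate a synthetic population grid
#'
#' Population as a Gaussian-kernel mixture around hotspot cities, rounded to
#' integers by the largest-remainder method so the grid sums exactly to the
#' requested total. If a land mask is supplied, population is placed on land
#' cells only.
#'
#' @param spec a [GridSpec-class]
#' @param total total population (persons, >= 0)
#' @param hotspots list of `list(lon=, lat=, weight=, sigma=)`; `sigma`
#'   (kernel scale, degrees) defaults to 0.3
#' @param seed integer seed (reserved; the mixture itself is deterministic)
#' @param land_mask optional logical `(lat, lon)` matrix, `TRUE` = land
#' @return a [PopulationGrid-class]
#' @export
generatePopulation <- function(spec, total, hotspots, seed = 1, land_mask = NULL) {
  stopifnot(is(spec, "GridSpec"), total >= 0)
  nlat <- length(latCentres(spec)); nlon <- length(lonCentres(spec))
  if (total == 0)
    return(new("PopulationGrid", grid = spec, count = matrix(0, nlat, nlon)))
  if (length(hotspots) == 0)
    contractStop("hotspot list must be non-empty when total > 0")
  lats <- latCentres(spec); lons <- lonCentres(spec)
  w <- matrix(0, nlat, nlon)
  for (h in hotspots) {
    if (is.null(h$sigma)) h$sigma <- 0.3
    if (h$weight < 0) contractStop("hotspot weights must be >= 0")
    d2 <- outer((lats - h$lat)^2, (lons - h$lon)^2, `+`)
    w <- w + h$weight * exp(-d2 / (2 * h$sigma^2))
  }
  if (!is.null(land_mask)) w[!land_mask] <- 0
  if (sum(w) == 0) contractStop("no cell received positive population weight")
  target <- total * w / sum(w)
  # largest-remainder rounding conserves the total exactly
  fl <- floor(target)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    idx <- order(target - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  new("PopulationGrid", grid = spec, count = fl)
}

# ---------------------------------------------------------------------------
# Vectorised field sampling used by the transport and dispersion modules:
# bilinear in space at the nearest stored time sample.
# ---------------------------------------------------------------------------

# Continuous fractional index of coordinates on centre-indexed axes.
# Returns list(i0, frac, ok); clamped to the valid interpolation range.
axisIndex <- function(x, x_min, cell, n) {
  pos <- (x - x_min) / cell + 0.5
  ok <- pos >= 0.5 - 1e-9 & pos <= n + 0.5 + 1e-9
  pos <- pmin(pmax(pos, 1), n)
  i0 <- pmin(floor(pos), n - 1)
  i0 <- pmax(i0, 1)
  list(i0 = i0, frac = pos - i0, ok = ok)
}

# Sample one variable of an EnvironmentFields at vectors of (lon, lat) and a
# single time index: bilinear in space, piecewise-constant (nearest) in time.
envSample <- function(fields, var, lon, lat, t_index) {
  spec <- fields@grid
  a <- slot(fields, var)
  nt <- dim(a)[1]
  t_index <- min(max(t_index, 1L), nt)
  ai <- axisIndex(lat, spec@lat_min, spec@cell_size, dim(a)[2])
  aj <- axisIndex(lon, spec@lon_min, spec@cell_size, dim(a)[3])
  sl <- a[t_index, , ]
  v00 <- sl[cbind(ai$i0, aj$i0)]
  v10 <- sl[cbind(ai$i0 + 1, aj$i0)]
  v01 <- sl[cbind(ai$i0, aj$i0 + 1)]
  v11 <- sl[cbind(ai$i0 + 1, aj$i0 + 1)]
  val <- v00 * (1 - ai$frac) * (1 - aj$frac) + v10 * ai$frac * (1 - aj$frac) +
    v01 * (1 - ai$frac) * aj$frac + v11 * ai$frac * aj$frac
  val[!(ai$ok & aj$ok)] <- NA_real_
  val
}

# TRUE where (lon, lat) falls on a land cell of the mask (nearest cell).
onLand <- function(mask, spec, lon, lat) {
  if (is.null(mask)) return(rep(FALSE, length(lon)))
  i <- round((lat - spec@lat_min) / spec@cell_size + 0.5)
  j <- round((lon - spec@lon_min) / spec@cell_size + 0.5)
  inside <- i >= 1 & i <= nrow(mask) & j >= 1 & j <= ncol(mask)
  out <- rep(FALSE, length(lon))
  # user-supplied masks may be 0/1 rasters rather than logical
  out[inside] <- mask[cbind(i[inside], j[inside])] != 0
  out
}
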