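#' @import methods
NULL

# ---------------------------------------------------------------------------
# GridSpec: regular lat-lon-time discretisation. Cell centres and time points
# are reproducible from the spec alone; arrays are ordered (time, lat, lon)
# with latitude and longitude ascending.
# ---------------------------------------------------------------------------

#' Regular latitude-longitude-time grid specification
#'
#' Defines the spatial and temporal discretisation used by all gridded
#' containers in the package. Cells are indexed by centre; arrays over a
#' `GridSpec` are ordered `(time, lat, lon)` with both coordinates ascending.
#'
#' @slot lat_min,lat_max,lon_min,lon_max domain bounds, decimal degrees (WGS84)
#' @slot cell_size cell edge, degrees
#' @slot t_start,t_end time span, `POSIXct` (UTC)
#' @slot t_step_h time step, hours
#' @export
setClass("GridSpec", representation(
  lat_min = "numeric", lat_max = "numeric",
  lon_min = "numeric", lon_max = "numeric",
  cell_size = "numeric",
  t_start = "POSIXct", t_end = "POSIXct",
  t_step_h = "numeric"
), validity = function(object) {
  msg <- character()
  if (object@lat_min >= object@lat_max) msg <- c(msg, "lat_min must be < lat_max")
  if (object@lon_min >= object@lon_max) msg <- c(msg, "lon_min must be < lon_max")
  if (object@cell_size <= 0) msg <- c(msg, "cell_size must be > 0")
  if (object@t_step_h <= 0) msg <- c(msg, "t_step_h must be > 0")
  if (object@t_start > object@t_end) msg <- c(msg, "t_start must be <= t_end")
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param lat_min,lat_max,lon_min,lon_max domain bounds in decimal degrees
#' @param cell_size cell edge in degrees
#' @param t_start,t_end time span (`POSIXct` or anything `as.POSIXct` accepts;
#'   interpreted as UTC)
#' @param t_step_h time step in hours
#' @return a [GridSpec-class] object
#' @examples
#' gridSpec(12, 17, 41, 44, 0.25, "2020-06-01", "2020-06-10", 1)
#' @export
gridSpec <- function(lat_min, lat_max, lon_min, lon_max, cell_size,
                     t_start, t_end, t_step_h = 1) {
  new("GridSpec",
      lat_min = as.numeric(lat_min), lat_max = as.numeric(lat_max),
      lon_min = as.numeric(lon_min), lon_max = as.numeric(lon_max),
      cell_size = as.numeric(cell_size),
      t_start = as.POSIXct(t_start, tz = "UTC"),
      t_end = as.POSIXct(t_end, tz = "UTC"),
      t_step_h = as.numeric(t_step_h))
}

# ---------------------------------------------------------------------------
# EnvironmentFields: wind/current/sst/salinity over a GridSpec.
# ---------------------------------------------------------------------------

#' Gridded environmental forcing fields
#'
#' Wind at 10 m, surface current, sea-surface temperature and salinity on a
#' common `(time, lat, lon)` grid. Drives spill transport, oil weathering and
#' atmospheric dispersion.
#'
#' @slot grid a [GridSpec-class]
#' @slot wind_u,wind_v 10-m wind components, m/s, arrays `(time, lat, lon)`
#' @slot current_u,current_v surface current components, m/s
#' @slot sst sea-surface temperature, degrees C
#' @slot salinity practical salinity units
#' @slot season one of `"summer"`, `"winter"`, `"spring"`, `"autumn"`
#' @export
setClass("EnvironmentFields", representation(
  grid = "GridSpec",
  wind_u = "array", wind_v = "array",
  current_u = "array", current_v = "array",
  sst = "array", salinity = "array",
  season = "character"
), validity = function(object) {
  msg <- character()
  dims <- gridDim(object@grid)
  for (nm in c("wind_u", "wind_v", "current_u", "current_v", "sst", "salinity")) {
    a <- slot(object, nm)
    if (!identical(dim(a), dims))
      msg <- c(msg, sprintf("%s has dim (%s), grid implies (%s)", nm,
                            paste(dim(a), collapse = ","), paste(dims, collapse = ",")))
    if (!all(is.finite(a))) msg <- c(msg, sprintf("%s contains non-finite values", nm))
  }
  spd_c <- sqrt(object@current_u^2 + object@current_v^2)
  spd_w <- sqrt(object@wind_u^2 + object@wind_v^2)
  if (any(spd_c > 3 + 1e-9)) msg <- c(msg, "current speed exceeds 3 m/s cap")
  if (any(spd_w > 40 + 1e-9)) msg <- c(msg, "wind speed exceeds 40 m/s cap")
  if (!object@season %in% c("summer", "winter", "spring", "autumn"))
    msg <- c(msg, "season must be summer/winter/spring/autumn")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# PopulationGrid: persons per cell, time-invariant.
# ---------------------------------------------------------------------------

#' Gridded population counts
#'
#' @slot grid a [GridSpec-class] (temporal slots ignored)
#' @slot count matrix `(lat, lon)` of persons per cell, non-negative
#' @export
setClass("PopulationGrid", representation(
  grid = "GridSpec", count = "matrix"
), validity = function(object) {
  msg <- character()
  dims <- gridDim(object@grid)[2:3]
  if (!identical(dim(object@count), dims))
    msg <- c(msg, "count matrix does not conform to grid")
  if (any(object@count < 0)) msg <- c(msg, "population counts must be >= 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SurfaceConcentrationField: sparse cell -> mean surface-oil value map.
# ---------------------------------------------------------------------------

#' Averaged surface-oil concentration field
#'
#' Per-cell ensemble-mean surface oil values keyed by latitude/longitude
#' rounded to a configured number of decimals. Cells never visited by any
#' simulation are absent, which is distinct from zero. The `units` slot is
#' `"thickness_m"` for raw fields and `"percentile"` after
#' [percentileTransform()].
#'
#' @slot cells data.frame with columns `lat`, `lon`, `value`
#' @slot decimals rounding used for the cell key (3 is roughly 100 m)
#' @slot n_simulations number of simulations averaged
#' @slot units `"thickness_m"` or `"percentile"`
#' @export
setClass("SurfaceConcentrationField", representation(
  cells = "data.frame", decimals = "numeric",
  n_simulations = "numeric", units = "character"
), validity = function(object) {
  msg <- character()
  if (!all(c("lat", "lon", "value") %in% names(object@cells)))
    msg <- c(msg, "cells needs columns lat, lon, value")
  else if (any(object@cells$value < 0)) msg <- c(msg, "cell values must be >= 0")
  if (!object@units %in% c("thickness_m", "percentile"))
    msg <- c(msg, "units must be thickness_m or percentile")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# UncertaintyRegion: convex hull of uncertainty-particle positions.
# ---------------------------------------------------------------------------

#' Convex trajectory-uncertainty region
#'
#' Minimal convex polygon containing every uncertainty-particle location from
#' all simulations; by construction of the perturbed ensemble it approximates
#' a 90% envelope of possible trajectories.
#'
#' @slot polygon matrix with columns `lon`, `lat` (closed ring)
#' @slot n_points number of particle locations enclosed
#' @slot coverage_note free-text provenance note
#' @export
setClass("UncertaintyRegion", representation(
  polygon = "matrix", n_points = "numeric", coverage_note = "character"
), validity = function(object) {
  if (nrow(object@polygon) < 4L) return("polygon ring needs >= 3 distinct vertices")
  if (!identical(colnames(object@polygon), c("lon", "lat")))
    return("polygon needs columns lon, lat")
  TRUE
})

# ---------------------------------------------------------------------------
# OilBudget: single-run mass-fraction time series.
# ---------------------------------------------------------------------------

#' Oil mass budget time series
#'
#' Hourly mass fractions by compartment for a single weathering/clean-up run.
#' Fractions sum to one at every step; the removal compartments are
#' cumulative, hence non-decreasing.
#'
#' @slot series data.frame with columns `time_h`, `floating`, `evaporated`,
#'   `skimmed`, `burned`, `dispersed`
#' @export
setClass("OilBudget", representation(series = "data.frame"),
  validity = function(object) {
    s <- object@series
    need <- c("time_h", "floating", "evaporated", "skimmed", "burned", "dispersed")
    if (!all(need %in% names(s))) return("series missing compartment columns")
    tot <- rowSums(s[, need[-1]])
    if (any(abs(tot - 1) > 1e-9)) return("compartment fractions must sum to 1 (1e-9)")
    if (any(unlist(s[, need[-1]]) < -1e-12)) return("fractions must be >= 0")
    TRUE
  })

#' Monte Carlo oil-fate ensemble summary
#'
#' Mean and 95% uncertainty band (2.5th/97.5th percentiles across draws) of
#' each oil compartment, plus the individual draws.
#'
#' @slot summary data.frame: `time_h`, then `<compartment>`,
#'   `lo95_<compartment>`, `hi95_<compartment>` for the five compartments
#' @slot draws numeric array `(draw, time, compartment)`
#' @slot n_mc number of Monte Carlo draws
#' @export
setClass("FateEnsemble", representation(
  summary = "data.frame", draws = "array", n_mc = "numeric"))

# ---------------------------------------------------------------------------
# PM25Field: 24-h average ground-level concentration per scenario.
# ---------------------------------------------------------------------------

#' Ground-level PM2.5 exposure field
#'
#' Ensemble-averaged 24-hour-average PM2.5 concentration on the environment
#' grid, with day-resolved fields over the emission window for person-day
#' accounting and an exact particle-mass audit.
#'
#' @slot grid a [GridSpec-class]
#' @slot values matrix `(lat, lon)`: 24-h average concentration, ug/m^3, over
#'   the final 24 h of the release
#' @slot daily array `(day, lat, lon)` of daily-average concentrations over
#'   the release window
#' @slot scenario list with at least `season`, `release_hours`, `mode`
#' @slot n_ensemble number of start times averaged
#' @slot conversion_rate oil-to-PM2.5 conversion rate used, ug/ug
#' @slot audit list: `emitted_ug`, `in_domain_ug`, `out_of_domain_ug`
#' @export
setClass("PM25Field", representation(
  grid = "GridSpec", values = "matrix", daily = "array",
  scenario = "list", n_ensemble = "numeric",
  conversion_rate = "numeric", audit = "list"
), validity = function(object) {
  if (any(!is.finite(object@values))) return("values must be finite")
  if (any(object@values < 0)) return("concentrations must be >= 0")
  TRUE
})
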