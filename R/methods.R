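# Accessor and show methods.

#' @rdname latCentres
#' @export
setMethod("latCentres", "GridSpec", function(spec) {
  n <- max(1L, round((spec@lat_max - spec@lat_min) / spec@cell_size))
  spec@lat_min + (seq_len(n) - 0.5) * spec@cell_size
})

#' @rdname lonCentres
#' @export
setMethod("lonCentres", "GridSpec", function(spec) {
  n <- max(1L, round((spec@lon_max - spec@lon_min) / spec@cell_size))
  spec@lon_min + (seq_len(n) - 0.5) * spec@cell_size
})

#' @rdname timePoints
#' @export
setMethod("timePoints", "GridSpec", function(spec) {
  seq(spec@t_start, spec@t_end, by = spec@t_step_h * 3600)
})

#' @rdname gridDim
#' @export
setMethod("gridDim", "GridSpec", function(spec) {
  c(length(timePoints(spec)), length(latCentres(spec)), length(lonCentres(spec)))
})

#' @rdname gridOf
#' @export
setMethod("gridOf", "EnvironmentFields", function(x) x@grid)
#' @rdname gridOf
#' @export
setMethod("gridOf", "PopulationGrid", function(x) x@grid)
#' @rdname gridOf
#' @export
setMethod("gridOf", "PM25Field", function(x) x@grid)

#' @rdname cellValues
#' @export
setMethod("cellValues", "SurfaceConcentrationField", function(x) x@cells)

#' @rdname fieldUnits
#' @export
setMethod("fieldUnits", "SurfaceConcentrationField", function(x) x@units)

#' @rdname nSimulations
#' @export
setMethod("nSimulations", "SurfaceConcentrationField", function(x) x@n_simulations)
#' @rdname nSimulations
#' @export
setMethod("nSimulations", "FateEnsemble", function(x) x@n_mc)
#' @rdname nSimulations
#' @export
setMethod("nSimulations", "PM25Field", function(x) x@n_ensemble)

#' @rdname budgetSeries
#' @export
setMethod("budgetSeries", "OilBudget", function(x) x@series)
#' @rdname budgetSeries
#' @export
setMethod("budgetSeries", "FateEnsemble", function(x) x@summary)

#' @rdname hullPolygon
#' @export
setMethod("hullPolygon", "UncertaintyRegion", function(x) x@polygon)

#' @rdname hullArea
#' @export
setMethod("hullArea", "UncertaintyRegion", function(x) {
  ring <- x@polygon[-nrow(x@polygon), , drop = FALSE]
  shoelaceArea(ring[, "lon"], ring[, "lat"])
})

#' @rdname populationCount
#' @export
setMethod("populationCount", "PopulationGrid", function(x) x@count)

#' @rdname pmValues
#' @export
setMethod("pmValues", "PM25Field", function(x) x@values)
#' @rdname pmDaily
#' @export
setMethod("pmDaily", "PM25Field", function(x) x@daily)
#' @rdname massAudit
#' @export
setMethod("massAudit", "PM25Field", function(x) x@audit)

setMethod("show", "GridSpec", function(object) {
  d <- gridDim(object)
  cat(sprintf("GridSpec: %.3g deg cells, lat [%g, %g], lon [%g, %g]\n",
              object@cell_size, object@lat_min, object@lat_max,
              object@lon_min, object@lon_max))
  cat(sprintf("  time: %s .. %s, step %g h  (%d x %d x %d)\n",
              format(object@t_start, tz = "UTC"), format(object@t_end, tz = "UTC"),
              object@t_step_h, d[1], d[2], d[3]))
})

setMethod("show", "EnvironmentFields", function(object) {
  cat(sprintf("EnvironmentFields (%s season)\n", object@season))
  show(object@grid)
  cat(sprintf("  mean |wind| %.2f m/s, mean |current| %.3f m/s, mean SST %.1f C\n",
              mean(sqrt(object@wind_u^2 + object@wind_v^2)),
              mean(sqrt(object@current_u^2 + object@current_v^2)),
              mean(object@sst)))
})

setMethod("show", "PopulationGrid", function(object) {
  cat(sprintf("PopulationGrid: %s persons over %d x %d cells\n",
              format(sum(object@count), big.mark = ","),
              nrow(object@count), ncol(object@count)))
})

setMethod("show", "SurfaceConcentrationField", function(object) {
  cat(sprintf("SurfaceConcentrationField: %d exposed cells (%d-decimal grid), %d simulations, units %s\n",
              nrow(object@cells), as.integer(object@decimals),
              as.integer(object@n_simulations), object@units))
})

setMethod("show", "UncertaintyRegion", function(object) {
  cat(sprintf("UncertaintyRegion: convex hull of %d particle locations, %d vertices, area %.4g deg^2\n",
              as.integer(object@n_points), nrow(object@polygon) - 1L, hullArea(object)))
  cat(" ", object@coverage_note, "\n")
})

setMethod("show", "OilBudget", function(object) {
  last <- object@series[nrow(object@series), ]
  cat(sprintf("OilBudget over %g h: floating %.1f%%, evaporated %.1f%%, removed %.1f%%\n",
              last$time_h, 100 * last$floating, 100 * last$evaporated,
              100 * (last$skimmed + last$burned + last$dispersed)))
})

setMethod("show", "FateEnsemble", function(object) {
  last <- object@summary[nrow(object@summary), ]
  cat(sprintf("FateEnsemble: %d Monte Carlo draws, %g h horizon\n",
              as.integer(object@n_mc), last$time_h))
  cat(sprintf("  floating at end: %.1f%% (95%% UI %.1f-%.1f%%)\n",
              100 * last$floating, 100 * last$lo95_floating, 100 * last$hi95_floating))
})

setMethod("show", "PM25Field", function(object) {
  cat(sprintf("PM25Field [%s, %g h release, %s]: max 24-h avg %.1f ug/m^3 over %d start times\n",
              object@scenario$season, object@scenario$release_hours,
              object@scenario$mode, max(object@values), as.integer(object@n_ensemble)))
})
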