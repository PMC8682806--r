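# Generics for the S4 containers. Accessors are preferred over direct slot
# access throughout the package and its documentation.

#' @rdname GridSpec-class
#' @param x an object with a grid
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))

#' Latitude cell centres of a grid
#' @param spec a [GridSpec-class]
#' @return numeric vector, ascending
#' @export
setGeneric("latCentres", function(spec) standardGeneric("latCentres"))

#' Longitude cell centres of a grid
#' @param spec a [GridSpec-class]
#' @return numeric vector, ascending
#' @export
setGeneric("lonCentres", function(spec) standardGeneric("lonCentres"))

#' Time points of a grid
#' @param spec a [GridSpec-class]
#' @return `POSIXct` vector
#' @export
setGeneric("timePoints", function(spec) standardGeneric("timePoints"))

#' Array dimension implied by a grid: (time, lat, lon)
#' @param spec a [GridSpec-class]
#' @return integer vector of length 3
#' @export
setGeneric("gridDim", function(spec) standardGeneric("gridDim"))

#' Per-cell values of a sparse concentration field
#' @param x a [SurfaceConcentrationField-class]
#' @return data.frame with columns `lat`, `lon`, `value`
#' @export
setGeneric("cellValues", function(x) standardGeneric("cellValues"))

#' Units of a field
#' @param x a field object
#' @export
setGeneric("fieldUnits", function(x) standardGeneric("fieldUnits"))

#' Number of simulations or draws behind a summary object
#' @param x a summary object
#' @export
setGeneric("nSimulations", function(x) standardGeneric("nSimulations"))

#' Budget time series of an oil-fate run
#' @param x an [OilBudget-class] or [FateEnsemble-class]
#' @return data.frame
#' @export
setGeneric("budgetSeries", function(x) standardGeneric("budgetSeries"))

#' Closed polygon ring of an uncertainty region
#' @param x an [UncertaintyRegion-class]
#' @return matrix with columns `lon`, `lat`
#' @export
setGeneric("hullPolygon", function(x) standardGeneric("hullPolygon"))

#' Polygon area of an uncertainty region (degrees^2, shoelace formula)
#' @param x an [UncertaintyRegion-class]
#' @export
setGeneric("hullArea", function(x) standardGeneric("hullArea"))

#' Population count matrix
#' @param x a [PopulationGrid-class]
#' @return matrix `(lat, lon)`
#' @export
setGeneric("populationCount", function(x) standardGeneric("populationCount"))

#' Ensemble-averaged PM2.5 concentration matrix
#' @param x a [PM25Field-class]
#' @return matrix `(lat, lon)`, ug/m^3
#' @export
setGeneric("pmValues", function(x) standardGeneric("pmValues"))

#' Daily-average PM2.5 fields over the release window
#' @param x a [PM25Field-class]
#' @return array `(day, lat, lon)`
#' @export
setGeneric("pmDaily", function(x) standardGeneric("pmDaily"))

#' Particle mass audit of a dispersion run
#' @param x a [PM25Field-class]
#' @return list with `emitted_ug`, `in_domain_ug`, `out_of_domain_ug`
#' @export
setGeneric("massAudit", function(x) standardGeneric("massAudit"))

#' Bilinear interpolation of a gridded field
#'
#' Standard bilinear weighting of the four cell centres surrounding each
#' query point. For sparse [SurfaceConcentrationField-class] objects, absent
#' neighbour cells are treated as zero; queries outside the populated
#' bounding box (padded by one cell) are an error.
#'
#' @param field a [SurfaceConcentrationField-class] or [PM25Field-class]
#' @param lon,lat query coordinates (vectorised)
#' @return numeric vector of interpolated values
#' @export
setGeneric("interpolateBilinear",
           function(field, lon, lat) standardGeneric("interpolateBilinear"))
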