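# Surface-concentration gridding, percentile transform, bilinear
# interpolation and the convex uncertainty region.

#' Grid particle snapshots into an ensemble-mean concentration field
#'
#' Each simulation's particles are binned onto cells keyed by coordinates
#' rounded (half-even) to `decimals`; per-cell values are summed within a
#' simulation, then averaged across all simulations, counting zero for
#' simulations that never touched a cell. Cells untouched by every
#' simulation are absent from the result (absence is distinct from zero).
#'
#' @param simulations list (one entry per simulation) of data.frames with
#'   columns `lon`, `lat`, `value`
#' @param decimals coordinate rounding (3 is roughly 100 m cells)
#' @return a [SurfaceConcentrationField-class] with units `"thickness_m"`
#' @export
gridConcentration <- function(simulations, decimals = 3) {
  if (length(simulations) == 0) contractStop("need at least one simulation")
  n_sim <- length(simulations)
  per_sim <- lapply(simulations, function(df) {
    if (nrow(df) == 0)
      return(data.frame(lat = numeric(), lon = numeric(), value = numeric()))
    key_lat <- round(df$lat, decimals)
    key_lon <- round(df$lon, decimals)
    agg <- stats::aggregate(df$value, by = list(lat = key_lat, lon = key_lon), FUN = sum)
    names(agg)[3] <- "value"
    agg
  })
  all <- do.call(rbind, per_sim)
  if (nrow(all) == 0) {
    cells <- data.frame(lat = numeric(), lon = numeric(), value = numeric())
  } else {
    cells <- stats::aggregate(all$value, by = list(lat = all$lat, lon = all$lon), FUN = sum)
    names(cells)[3] <- "value"
    cells$value <- cells$value / n_sim  # zero for sims that missed the cell
    cells <- cells[order(cells$lat, cells$lon), ]
    rownames(cells) <- NULL
  }
  new("SurfaceConcentrationField", cells = cells, decimals = decimals,
      n_simulations = n_sim, units = "thickness_m")
}

#' Transform a concentration field to percentile ranks
#'
#' Maps each exposed cell's value to its percentile rank among all exposed
#' cells: `100 * (fraction of exposed cells with value <= x)`. Ties share the
#' highest rank; ranks are invariant under strictly monotone rescaling of
#' the values. Used because the absolute spilled volume is uncertain while
#' relative exposure is informative.
#'
#' @param field a [SurfaceConcentrationField-class] with raw values
#' @return the field with values replaced by percentiles and units
#'   `"percentile"`
#' @export
percentileTransform <- function(field) {
  stopifnot(is(field, "SurfaceConcentrationField"))
  cells <- field@cells
  if (nrow(cells) == 0) contractStop("cannot percentile-transform an empty field")
  v <- cells$value
  # fraction of exposed cells with value <= x; ties share the highest rank
  cells$value <- 100 * rank(v, ties.method = "max") / length(v)
  new("SurfaceConcentrationField", cells = cells, decimals = field@decimals,
      n_simulations = field@n_simulations, units = "percentile")
}

# shared bilinear core over a sparse rounded-cell lookup
sparseBilinear <- function(cells, decimals, lon, lat) {
  h <- 10^(-decimals)
  keys <- paste(round(cells$lat / h), round(cells$lon / h))
  lookup <- cells$value
  names(lookup) <- keys
  get0v <- function(ki, kj) {
    v <- lookup[paste(ki, kj)]
    ifelse(is.na(v), 0, v)
  }
  ti <- lat / h; tj <- lon / h
  i0 <- floor(ti + 1e-9); fi <- ti - i0
  j0 <- floor(tj + 1e-9); fj <- tj - j0
  v00 <- get0v(i0, j0); v10 <- get0v(i0 + 1, j0)
  v01 <- get0v(i0, j0 + 1); v11 <- get0v(i0 + 1, j0 + 1)
  unname(v00 * (1 - fi) * (1 - fj) + v10 * fi * (1 - fj) +
           v01 * (1 - fi) * fj + v11 * fi * fj)
}

#' @rdname interpolateBilinear
#' @export
setMethod("interpolateBilinear", "SurfaceConcentrationField",
  function(field, lon, lat) {
    cells <- field@cells
    if (nrow(cells) == 0) contractStop("empty field")
    h <- 10^(-field@decimals)
    if (any(lat < min(cells$lat) - h | lat > max(cells$lat) + h |
            lon < min(cells$lon) - h | lon > max(cells$lon) + h))
      contractStop("query outside the populated field domain")
    sparseBilinear(cells, field@decimals, lon, lat)
  })

#' @rdname interpolateBilinear
#' @export
setMethod("interpolateBilinear", "PM25Field", function(field, lon, lat) {
  spec <- field@grid
  m <- field@values
  ai <- axisIndex(lat, spec@lat_min, spec@cell_size, nrow(m))
  aj <- axisIndex(lon, spec@lon_min, spec@cell_size, ncol(m))
  if (any(!ai$ok | !aj$ok)) contractStop("query outside the field domain")
  v00 <- m[cbind(ai$i0, aj$i0)]; v10 <- m[cbind(ai$i0 + 1, aj$i0)]
  v01 <- m[cbind(ai$i0, aj$i0 + 1)]; v11 <- m[cbind(ai$i0 + 1, aj$i0 + 1)]
  v00 * (1 - ai$frac) * (1 - aj$frac) + v10 * ai$frac * (1 - aj$frac) +
    v01 * (1 - ai$frac) * aj$frac + v11 * ai$frac * aj$frac
})

#' Convex uncertainty region from particle locations
#'
#' Minimal convex polygon (convex hull) containing every uncertainty-particle
#' location; with the perturbed-forcing ensemble this envelope approximates a
#' 90% region of possible spill trajectories.
#'
#' @param points matrix or data.frame with columns `lon`, `lat` (at least 3
#'   non-collinear points)
#' @return an [UncertaintyRegion-class]
#' @export
uncertaintyRegion <- function(points) {
  pts <- as.matrix(points[, c("lon", "lat")])
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  uni <- unique(pts)
  if (nrow(uni) < 3) contractStop("degenerate geometry: need >= 3 distinct points")
  idx <- grDevices::chull(pts[, "lon"], pts[, "lat"])
  if (length(idx) < 3) contractStop("degenerate geometry: points are collinear")
  ring <- pts[idx, , drop = FALSE]
  if (shoelaceArea(ring[, "lon"], ring[, "lat"]) <= 0)
    contractStop("degenerate geometry: points are collinear")
  ring <- rbind(ring, ring[1, , drop = FALSE])  # closed ring
  colnames(ring) <- c("lon", "lat")
  new("UncertaintyRegion", polygon = ring, n_points = nrow(pts),
      coverage_note = "approximately 90% of trajectories")
}

#' Accumulate weekly fields into cumulative spill footprints
#'
#' "Reached by the spill at week w" is cumulative: a cell counts as reached
#' once oil has been present in it at any week mark up to w. Returns, for
#' each week, the union of cells over weeks 1..w with each cell carrying its
#' maximum weekly mean value, so footprint-based estimators (fishery loss,
#' plant disruption) grow monotonically with a growing spill.
#'
#' @param fields named list of weekly [SurfaceConcentrationField-class]
#'   objects, in week order
#' @return named list of cumulative fields, same names
#' @export
accumulateFields <- function(fields) {
  acc <- NULL
  out <- vector("list", length(fields))
  names(out) <- names(fields)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    cells <- cellValues(f)
    if (is.null(acc)) acc <- cells
    else {
      m <- merge(acc, cells, by = c("lat", "lon"), all = TRUE)
      m$value <- pmax(m$value.x, m$value.y, na.rm = TRUE)
      acc <- m[, c("lat", "lon", "value")]
    }
    acc <- acc[order(acc$lat, acc$lon), ]
    rownames(acc) <- NULL
    out[[nm]] <- new("SurfaceConcentrationField", cells = acc,
                     decimals = f@decimals, n_simulations = f@n_simulations,
                     units = f@units)
  }
  out
}

#' Point-in-region test for an uncertainty region
#'
#' @param region an [UncertaintyRegion-class]
#' @param lon,lat query coordinates (vectorised)
#' @param tol boundary tolerance in degrees
#' @return logical vector, `TRUE` when the point lies inside or on the hull
#' @export
regionContains <- function(region, lon, lat, tol = 1e-9) {
  ring <- region@polygon
  nv <- nrow(ring) - 1L
  inside <- rep(TRUE, length(lon))
  # convex polygon: point is inside iff it is on the inner side of every edge
  orient <- sign(shoelaceOrient(ring))
  for (e in seq_len(nv)) {
    ax <- ring[e, "lon"]; ay <- ring[e, "lat"]
    bx <- ring[e + 1, "lon"]; by <- ring[e + 1, "lat"]
    cross <- (bx - ax) * (lat - ay) - (by - ay) * (lon - ax)
    inside <- inside & (orient * cross >= -tol)
  }
  inside
}

# signed area (positive = counter-clockwise ring)
shoelaceOrient <- function(ring) {
  n <- nrow(ring) - 1L
  x <- ring[seq_len(n), "lon"]; y <- ring[seq_len(n), "lat"]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Export a concentration field as CSV
#'
#' Writes `(lat, lon, mean_value, percentile)` for every exposed cell.
#'
#' @param field a raw (thickness) [SurfaceConcentrationField-class]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeConcentrationCSV <- function(field, path) {
  pc <- percentileTransform(field)
  out <- field@cells
  names(out)[3] <- "mean_value"
  out$percentile <- pc@cells$value
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export an uncertainty region as GeoJSON
#'
#' @param region an [UncertaintyRegion-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeRegionGeoJSON <- function(region, path) {
  ring <- region@polygon
  coords <- lapply(seq_len(nrow(ring)), function(i) c(ring[i, "lon"], ring[i, "lat"]))
  obj <- list(type = "Feature",
              geometry = list(type = "Polygon", coordinates = list(coords)),
              properties = list(coverage_note = region@coverage_note,
                                n_points = region@n_points))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}
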