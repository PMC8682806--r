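# Gridded-field and asset-layer I/O.
#
# Gridded fields travel in a self-describing JSON container: a header block
# with the grid definition and a variables block keyed by CF-like names
# (u10, v10, water_u, water_v, water_temp, salinity), each carrying units and
# an array ordered (time, lat, lon). Doubles are written at full precision so
# a write/read round trip is bit-exact.

ENV_VARS <- c(wind_u = "u10", wind_v = "v10",
              current_u = "water_u", current_v = "water_v",
              sst = "water_temp", salinity = "salinity")
ENV_UNITS <- c(u10 = "m s-1", v10 = "m s-1", water_u = "m s-1",
               water_v = "m s-1", water_temp = "degC", salinity = "psu")

#' Write environmental fields to a self-describing JSON file
#'
#' Numbers are emitted at 17 significant digits so that a write/read round
#' trip reproduces every double bit-exactly. Arrays are stored flat in
#' column-major order with an explicit `shape` of `(time, lat, lon)`.
#'
#' @param fields an [EnvironmentFields-class]
#' @param path output file path
#' @param lat_descending write the latitude axis (and data) north-to-south,
#'   as some external producers do; [readEnvironment()] normalises either
#'   orientation to ascending
#' @return `path`, invisibly
#' @seealso [readEnvironment()]
#' @export
writeEnvironment <- function(fields, path, lat_descending = FALSE) {
  stopifnot(is(fields, "EnvironmentFields"))
  spec <- fields@grid
  lat <- latCentres(spec)
  idx <- if (lat_descending) rev(seq_along(lat)) else seq_along(lat)
  num <- function(x) sprintf("%.17g", x)
  arr <- function(x) paste0("[", paste(num(x), collapse = ","), "]")
  strv <- function(x) paste0("[", paste0('"', x, '"', collapse = ","), "]")
  shape <- gridDim(spec)
  vars <- vapply(names(ENV_VARS), function(slotnm) {
    v <- unname(ENV_VARS[slotnm])
    a <- slot(fields, slotnm)[, idx, , drop = FALSE]
    sprintf('"%s":{"units":"%s","data":%s}', v, ENV_UNITS[v], arr(as.vector(a)))
  }, "")
  txt <- paste0(
    '{"format":"spillimpact-gridded-v1",',
    '"season":"', fields@season, '",',
    '"grid":{"lat":', arr(lat[idx]),
    ',"lon":', arr(lonCentres(spec)),
    ',"cell_size":', num(spec@cell_size),
    ',"time":', strv(format(timePoints(spec), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
    ',"t_step_h":', num(spec@t_step_h), "},",
    '"dims":["time","lat","lon"],',
    '"shape":[', paste(shape, collapse = ","), "],",
    '"variables":{', paste(vars, collapse = ","), "}}")
  writeLines(txt, path)
  invisible(path)
}

#' Read environmental fields from a self-describing JSON file
#'
#' Validates that all six variables are present with the declared units, and
#' normalises a descending latitude axis to ascending (re-ordering the data
#' consistently).
#'
#' @param path file written by [writeEnvironment()] or an external producer
#'   using the same container
#' @return an [EnvironmentFields-class]
#' @export
readEnvironment <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  missing <- setdiff(unname(ENV_VARS), names(obj$variables))
  if (length(missing))
    contractStop("missing variable: ", paste(missing, collapse = ", "))
  for (v in unname(ENV_VARS)) {
    got <- obj$variables[[v]]$units
    if (!identical(got, unname(ENV_UNITS[v])))
      contractStop(sprintf("unit mismatch for %s: expected '%s', got '%s'",
                           v, ENV_UNITS[v], got))
  }
  lat <- obj$grid$lat; lon <- obj$grid$lon
  lat_order <- order(lat); lon_order <- order(lon)
  lat <- lat[lat_order]; lon <- lon[lon_order]
  cs <- obj$grid$cell_size
  tp <- as.POSIXct(obj$grid$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  spec <- gridSpec(lat[1] - cs / 2, lat[length(lat)] + cs / 2,
                   lon[1] - cs / 2, lon[length(lon)] + cs / 2,
                   cs, tp[1], tp[length(tp)], obj$grid$t_step_h)
  if (!isTRUE(all.equal(latCentres(spec), lat, tolerance = 1e-8)))
    contractStop("grid mismatch: latitude centres are not a regular grid")
  shape <- obj$shape
  arr <- function(v) {
    flat <- obj$variables[[v]]$data
    if (length(flat) != prod(shape))
      contractStop("grid mismatch: ", v, " does not fill (time, lat, lon)")
    array(flat, dim = shape)[, lat_order, lon_order, drop = FALSE]
  }
  new("EnvironmentFields", grid = spec,
      wind_u = arr("u10"), wind_v = arr("v10"),
      current_u = arr("water_u"), current_v = arr("water_v"),
      sst = arr("water_temp"), salinity = arr("salinity"),
      season = if (is.null(obj$season)) "summer" else obj$season)
}

# ---------------------------------------------------------------------------
# Asset layers: ports, desalination plants (GeoJSON points), fishery yield
# grid (data.frame). Kept as plain validated lists/data.frames; these are
# small tabular inputs, not simulation state.
# ---------------------------------------------------------------------------

#' Construct an asset layer
#'
#' @param ports data.frame: `name`, `lon`, `lat`, `food_aid_share` (fraction
#'   of national food aid entering through the port), `monthly_fuel_tons`
#' @param desalination data.frame: `name`, `lon`, `lat`, `capacity_m3_per_day`
#'   (may be `NA` for plants with unknown capacity), `country`
#' @param fishery data.frame: `lat`, `lon`, `yield_tons`, `region`
#'   (`"Red Sea"` or `"Gulf of Aden"`)
#' @return validated list of class `"assetLayer"`
#' @export
assetLayer <- function(ports, desalination, fishery) {
  stopifnot(all(c("name", "lon", "lat", "food_aid_share", "monthly_fuel_tons") %in% names(ports)),
            all(c("name", "lon", "lat", "capacity_m3_per_day", "country") %in% names(desalination)),
            all(c("lat", "lon", "yield_tons", "region") %in% names(fishery)))
  if (any(ports$food_aid_share < 0 | ports$food_aid_share > 1))
    contractStop("food_aid_share must be in [0, 1]")
  if (any(desalination$capacity_m3_per_day < 0, na.rm = TRUE))
    contractStop("capacities must be >= 0")
  if (any(fishery$yield_tons < 0)) contractStop("fishery yield must be >= 0")
  structure(list(ports = ports, desalination = desalination, fishery = fishery),
            class = "assetLayer")
}

#' Write point assets as GeoJSON
#'
#' Ports and desalination plants are written as one GeoJSON FeatureCollection
#' of points; fishery yield goes to a CSV alongside (`<path>.fishery.csv`).
#'
#' @param assets an [assetLayer()]
#' @param path GeoJSON output path
#' @return `path`, invisibly
#' @export
writeAssets <- function(assets, path) {
  feat <- function(row, kind, props) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(row$lon, row$lat)),
         properties = c(list(kind = kind, name = row$name), props))
  }
  features <- c(
    lapply(seq_len(nrow(assets$ports)), function(i) {
      r <- assets$ports[i, ]
      feat(r, "port", list(food_aid_share = r$food_aid_share,
                           monthly_fuel_tons = r$monthly_fuel_tons))
    }),
    lapply(seq_len(nrow(assets$desalination)), function(i) {
      r <- assets$desalination[i, ]
      feat(r, "desalination",
           list(capacity_m3_per_day = r$capacity_m3_per_day, country = r$country))
    }))
  fc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(fc, digits = NA, auto_unbox = TRUE,
                              null = "null", na = "null"), path)
  utils::write.csv(assets$fishery, paste0(path, ".fishery.csv"), row.names = FALSE)
  invisible(path)
}

#' Read point assets from GeoJSON
#'
#' @param path GeoJSON written by [writeAssets()] (expects the companion
#'   `<path>.fishery.csv`)
#' @return an [assetLayer()]
#' @export
readAssets <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(fc$features, function(f) {
    p <- f$properties
    data.frame(kind = p$kind, name = p$name,
               lon = f$geometry$coordinates[[1]], lat = f$geometry$coordinates[[2]],
               food_aid_share = if (is.null(p$food_aid_share)) NA_real_ else p$food_aid_share,
               monthly_fuel_tons = if (is.null(p$monthly_fuel_tons)) NA_real_ else p$monthly_fuel_tons,
               capacity_m3_per_day = if (is.null(p$capacity_m3_per_day)) NA_real_ else p$capacity_m3_per_day,
               country = if (is.null(p$country)) NA_character_ else p$country)
  })
  all <- do.call(rbind, rows)
  fishery <- utils::read.csv(paste0(path, ".fishery.csv"), stringsAsFactors = FALSE)
  assetLayer(
    ports = all[all$kind == "port",
                c("name", "lon", "lat", "food_aid_share", "monthly_fuel_tons")],
    desalination = all[all$kind == "desalination",
                       c("name", "lon", "lat", "capacity_m3_per_day", "country")],
    fishery = fishery)
}
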