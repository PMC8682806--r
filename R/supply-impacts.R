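# Downstream disruption estimators over the concentration fields and asset
# layers: port exposure, desalination capacity, fuel imports, fuel prices,
# food aid, fishery yield.

#' Port exposure to surface oil
#'
#' Bilinearly interpolates the percentile-transformed concentration field at
#' each port; a port is directly impacted when its interpolated percentile
#' meets the threshold (default the 90th percentile among exposed areas).
#' Ports outside the exposed domain are flagged unexposed with a warning
#' status rather than an error.
#'
#' @param field a percentile-transformed [SurfaceConcentrationField-class]
#' @param ports data.frame with `name`, `lon`, `lat`
#' @param threshold_percentile exposure threshold, default 90
#' @param radius_deg harbour extent in degrees: when positive, the port also
#'   counts oil cells within this box radius (a harbour and its approaches
#'   span kilometres, and desk-scale ensembles leave single-cell gaps that a
#'   point query would fall through); 0 = pure point interpolation
#' @return data.frame: `name`, `percentile`, `reached` (any oil present:
#'   the port-closure criterion), `exposed` (percentile at or above the
#'   threshold: the "directly impacted" designation), `status`
#' @export
portExposure <- function(field, ports, threshold_percentile = 90,
                         radius_deg = 0) {
  if (fieldUnits(field) != "percentile")
    contractStop("field must be percentile-transformed")
  cells <- cellValues(field)
  out <- data.frame(name = ports$name, percentile = NA_real_,
                    reached = FALSE, exposed = FALSE, status = "ok",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ports))) {
    p <- tryCatch(interpolateBilinear(field, ports$lon[i], ports$lat[i]),
                  error = function(e) NA_real_)
    if (radius_deg > 0) {
      near <- abs(cells$lat - ports$lat[i]) <= radius_deg &
        abs(cells$lon - ports$lon[i]) <= radius_deg
      if (any(near)) p <- max(p, cells$value[near], na.rm = TRUE)
    }
    if (is.na(p)) {
      out$status[i] <- "outside_domain"
      out$percentile[i] <- 0
    } else {
      out$percentile[i] <- p
      out$reached[i] <- p > 0
      out$exposed[i] <- p >= threshold_percentile
    }
  }
  out
}

#' Desalination-plant disruption and population equivalents
#'
#' A plant is disrupted when any oil is present at its location (positive
#' interpolated concentration on the raw field). Plants with unknown
#' capacity receive an equal share of their country's total capacity
#' (equal-division rule, conserving the country total exactly). The
#' population equivalent divides disrupted capacity by per-capita daily use.
#'
#' @param field a raw (thickness) [SurfaceConcentrationField-class]
#' @param plants data.frame: `name`, `lon`, `lat`, `capacity_m3_per_day`
#'   (NA = unknown), `country`
#' @param per_capita_use named vector, m^3 per person per day by country
#' @param country_capacity named vector: total capacity by country used to
#'   fill unknown plant capacities
#' @param radius_deg intake extent in degrees (see [portExposure()]);
#'   0 = pure point interpolation
#' @return list: `plants` (with filled capacity and `disrupted`),
#'   `total_disrupted_m3_day`, `population_equivalent`
#' @export
desalDisruption <- function(field, plants, per_capita_use,
                            country_capacity = NULL, radius_deg = 0) {
  if (any(per_capita_use <= 0)) contractStop("per-capita use must be > 0")
  plants <- as.data.frame(plants)
  for (ctry in unique(plants$country)) {
    sel <- plants$country == ctry & is.na(plants$capacity_m3_per_day)
    if (any(sel)) {
      if (is.null(country_capacity) || is.na(country_capacity[ctry]))
        contractStop("unknown plant capacities need a country_capacity for ", ctry)
      n_known <- sum(plants$country == ctry)
      plants$capacity_m3_per_day[sel] <- country_capacity[ctry] / n_known
    }
  }
  cells <- cellValues(field)
  conc <- vapply(seq_len(nrow(plants)), function(i) {
    v <- tryCatch(interpolateBilinear(field, plants$lon[i], plants$lat[i]),
                  error = function(e) 0)
    if (radius_deg > 0) {
      near <- abs(cells$lat - plants$lat[i]) <= radius_deg &
        abs(cells$lon - plants$lon[i]) <= radius_deg
      if (any(near)) v <- max(v, cells$value[near])
    }
    v
  }, numeric(1))
  plants$disrupted <- conc > 0
  total <- sum(plants$capacity_m3_per_day[plants$disrupted])
  pe <- sum(vapply(which(plants$disrupted), function(i) {
    plants$capacity_m3_per_day[i] / per_capita_use[plants$country[i]]
  }, numeric(1)))
  list(plants = plants, total_disrupted_m3_day = total,
       population_equivalent = unname(pe))
}

#' Monthly fuel-import disruption
#'
#' Mean and 95% uncertainty interval (linear-interpolation sample quantiles)
#' of the monthly fuel tonnage routed through the disrupted ports.
#'
#' @param monthly_imports numeric vector of monthly import tonnages (n >= 2)
#' @return list: `mean`, `lo95`, `hi95` (metric tons per month)
#' @export
fuelDisruption <- function(monthly_imports) {
  if (length(monthly_imports) < 2) contractStop("need at least 2 monthly values")
  q <- linearQuantile(monthly_imports)
  list(mean = mean(monthly_imports), lo95 = q[1], hi95 = q[2])
}

#' Fuel price spike between two dates
#'
#' `100 * (median(t1) - median(t0)) / median(t0)` across fuel types present
#' at both dates.
#'
#' @param prices_t0,prices_t1 named numeric vectors of prices by fuel type
#' @return percent change of the median price
#' @export
priceSpike <- function(prices_t0, prices_t1) {
  common <- intersect(names(prices_t0), names(prices_t1))
  if (length(common) < 1) contractStop("need at least one fuel present at both dates")
  m0 <- stats::median(prices_t0[common])
  m1 <- stats::median(prices_t1[common])
  if (m0 == 0) contractStop("zero baseline median price")
  100 * (m1 - m0) / m0
}

#' Food-aid disruption from port closures
#'
#' Point estimate: combined food-aid share of the disrupted ports times the
#' mean of the monthly people-targeted-for-assistance series; the
#' uncertainty interval multiplies the share by the series' 2.5th/97.5th
#' linear-interpolation quantiles.
#'
#' @param port_shares named vector of food-aid shares (fractions) per port
#' @param targeted_series monthly persons targeted for food assistance
#'   (n >= 2)
#' @param disrupted_ports character vector of disrupted port names
#' @return list: `share`, `mean`, `lo95`, `hi95` (persons)
#' @export
foodAidDisruption <- function(port_shares, targeted_series, disrupted_ports) {
  if (length(targeted_series) < 1) contractStop("empty targeted series")
  if (any(port_shares < 0 | port_shares > 1))
    contractStop("shares must be in [0, 1]")
  share <- sum(port_shares[names(port_shares) %in% disrupted_ports])
  if (share == 0 || length(disrupted_ports) == 0)
    return(list(share = 0, mean = 0, lo95 = 0, hi95 = 0))
  if (length(targeted_series) < 2) contractStop("need at least 2 monthly values")
  q <- linearQuantile(targeted_series)
  list(share = share, mean = share * mean(targeted_series),
       lo95 = share * q[1], hi95 = share * q[2])
}

#' Fishery-yield loss from spill coverage
#'
#' Sums regional fishery yield over grid cells reached by the spill, where
#' "reached" keeps only cells whose surface-oil percentile meets the
#' threshold (`"none"`, `"p10"` or `"p20"`; the percentile threshold
#' excludes trace-amount cells), and reports the threatened share of the
#' regional total.
#'
#' @param field a raw (thickness) [SurfaceConcentrationField-class]; the
#'   percentile threshold is applied to its percentile transform
#' @param yield_grid data.frame: `lat`, `lon`, `yield_tons`, `region`
#' @param region region to assess (e.g. `"Red Sea"`)
#' @param threshold `"none"`, `"p10"` or `"p20"`
#' @return list: `threatened_fraction` (percent), `threatened_tons`,
#'   `regional_tons`, `threshold`
#' @export
fisheryLoss <- function(field, yield_grid, region = "Red Sea",
                        threshold = c("p10", "none", "p20")) {
  threshold <- match.arg(threshold)
  reg <- yield_grid[yield_grid$region == region, ]
  total <- sum(reg$yield_tons)
  if (total == 0) contractStop("zero regional fishery yield")
  cells <- cellValues(field)
  if (nrow(cells) == 0)
    return(list(threatened_fraction = 0, threatened_tons = 0,
                regional_tons = total, threshold = threshold))
  pc <- percentileTransform(field)
  cut <- switch(threshold, none = 0, p10 = 10, p20 = 20)
  keep <- cellValues(pc)$value >= cut
  # co-register on the yield grid's resolution: a yield cell is reached when
  # a retained oil cell falls nearest to it
  step_lat <- resolutionOf(reg$lat); step_lon <- resolutionOf(reg$lon)
  lat0 <- min(reg$lat); lon0 <- min(reg$lon)
  oil_key <- paste(round((cells$lat[keep] - lat0) / step_lat),
                   round((cells$lon[keep] - lon0) / step_lon))
  reg_key <- paste(round((reg$lat - lat0) / step_lat),
                   round((reg$lon - lon0) / step_lon))
  hit <- reg_key %in% oil_key
  threatened <- sum(reg$yield_tons[hit])
  list(threatened_fraction = 100 * threatened / total,
       threatened_tons = threatened, regional_tons = total,
       threshold = threshold)
}

# smallest positive spacing of a coordinate vector (grid resolution)
resolutionOf <- function(x) {
  u <- sort(unique(round(x, 9)))
  if (length(u) < 2) return(1)
  min(diff(u))
}
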