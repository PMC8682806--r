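# Internal helpers shared across modules.

EARTH_M_PER_DEG_LAT <- 111320

#' Metres per degree of longitude at a given latitude
#' @param lat latitude in decimal degrees
#' @return metres per degree of longitude
#' @keywords internal
metresPerDegLon <- function(lat) EARTH_M_PER_DEG_LAT * cos(lat * pi / 180)

#' Linear-interpolation sample quantiles
#'
#' The single quantile convention used throughout the package: type-7
#' (linear interpolation between order statistics), the default of
#' [stats::quantile()].
#'
#' @param x numeric vector
#' @param probs probabilities
#' @return unnamed numeric vector of quantiles
#' @export
linearQuantile <- function(x, probs = c(0.025, 0.975)) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

#' Derive a stage seed from a global seed
#'
#' Deterministic seed splitting so pipeline stages are individually
#' reproducible: a small multiplicative hash of the stage name folded into
#' the global seed, kept below 2^31.
#'
#' @param seed global integer seed
#' @param stage character stage name
#' @return integer seed
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 1000003L
  as.integer((abs(seed) %% 1000003L) * 1009L + h) %% 2147483647L
}

#' Shoelace polygon area
#' @param lon,lat polygon vertex coordinates (ring need not be closed)
#' @return absolute area in the coordinate units squared
#' @keywords internal
shoelaceArea <- function(lon, lat) {
  n <- length(lon)
  j <- c(n, seq_len(n - 1L))
  abs(sum(lon[j] * lat - lon * lat[j])) / 2
}

# stop() with a consistent prefix for contract violations
contractStop <- function(...) stop(..., call. = FALSE)
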