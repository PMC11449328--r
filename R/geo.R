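#' Great-circle (haversine) distance between GPS fixes
#'
#' Distance in meters between pairs of WGS84 coordinates, computed with the
#' haversine formula on a sphere of radius 6,371,000 m. All meter-valued
#' geometry in the package goes through this radius so that distances,
#' speeds, and stay-point thresholds are mutually consistent.
#'
#' @param lat1,lon1 numeric vectors, degrees.
#' @param lat2,lon2 numeric vectors, degrees (recycled against the first pair).
#' @return numeric vector of distances in meters.
#' @examples
#' haversine_m(52, 11, 53, 11)  # one degree of latitude, ~111.19 km
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  stopifnot(is.finite(lat1), is.finite(lon1), is.finite(lat2), is.finite(lon2))
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("latitude must lie in [-90, 90] and longitude in [-180, 180]")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000)
}

#' @rdname haversine_m
#' @param fixes data frame with `lat` and `lon` columns (consecutive fixes).
#' @return `path_length_m()`: total length in meters of the polyline through
#'   the fixes, i.e. the sum of haversine distances of adjacent coordinates.
#' @export
path_length_m <- function(fixes) {
  n <- nrow(fixes)
  if (is.null(n) || n < 2) return(0)
  sum(haversine_m(fixes$lat[-n], fixes$lon[-n], fixes$lat[-1], fixes$lon[-1]))
}

# meters per degree of latitude at the package radius (pi * R / 180)
.M_PER_DEG <- pi * 6371000 / 180

# Local tangent (equirectangular) frame anchored at (lat0, lon0): x east,
# y north, both in meters. Used by the simulator so that GPS noise and
# detour geometry are specified in meters and mapped back to lat/lon.
.to_local <- function(lat, lon, lat0, lon0) {
  cbind(x = (lon - lon0) * cos(lat0 * pi / 180) * .M_PER_DEG,
        y = (lat - lat0) * .M_PER_DEG)
}

.from_local <- function(x, y, lat0, lon0) {
  cbind(lat = lat0 + y / .M_PER_DEG,
        lon = lon0 + x / (cos(lat0 * pi / 180) * .M_PER_DEG))
}

# Deterministic substream seed for participant p, track k under master seed.
# Keeps every derived seed in [1, 2^31 - 2] so cohorts are reproducible
# under parallel generation.
.derive_seed <- function(master, p_index, track_id = 0L) {
  (as.numeric(master) * 48271 + p_index * 1299709 + track_id * 7919) %%
    2147483646 + 1
}
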