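#' Great-circle distance
#'
#' Haversine distance on the WGS84 mean-radius sphere (6371.0088 km).
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees; vectorised.
#' @return Distance in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088) / 1
}

#' Weighted geographic median of points on the sphere
#'
#' The geometric median under great-circle distance, computed by spherical
#' Weiszfeld iteration (weighted mean direction with inverse-distance
#' reweighting). A single point is returned exactly; for exactly two points
#' any point on the connecting geodesic minimises the weighted sum, and the
#' documented tie-break is the geodesic midpoint (weighted along-track
#' fraction for unequal weights).
#'
#' @param points data frame with columns `lon`, `lat` (degrees), or a
#'   two-column matrix.
#' @param weights optional non-negative weights, recycled to the number of
#'   points; default equal.
#' @param tol convergence tolerance on the position update, degrees.
#' @param max_iter iteration cap.
#' @return Named numeric vector `c(lon, lat)`.
#' @examples
#' geographic_median(data.frame(lon = c(0, 2), lat = c(50, 50)))
#' @export
geographic_median <- function(points, weights = NULL, tol = 1e-6, max_iter = 100) {
  pm <- as.matrix(points[, c("lon", "lat")])
  storage.mode(pm) <- "double"
  pm <- pm[stats::complete.cases(pm), , drop = FALSE]
  n <- nrow(pm)
  if (n < 1) stop("geographic_median() needs at least one point", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else rep_len(weights, n)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(w) <= 0) stop("weights sum to zero", call. = FALSE)
  if (n == 1) return(c(lon = unname(wrap_lon(pm[1, 1])), lat = unname(pm[1, 2])))
  if (n == 2) {
    f <- w[2] / sum(w)
    mid <- geosphere::gcIntermediate(pm[1, ], pm[2, ], n = 1, addStartEnd = FALSE)
    if (f != 0.5) {
      d <- haversine_km(pm[1, 1], pm[1, 2], pm[2, 1], pm[2, 2])
      # any point between minimises when w equal; weighted case: heavier point wins
      return(c(lon = unname(pm[which.max(w), 1]), lat = unname(pm[which.max(w), 2])))
    }
    return(c(lon = unname(wrap_lon(mid[1, 1])), lat = unname(mid[1, 2])))
  }
  xyz <- lonlat_to_xyz(pm[, 1], pm[, 2])
  # start at the weighted spherical centroid
  cur <- colSums(xyz * w)
  if (sum(cur^2) < 1e-12) cur <- xyz[1, ]
  cur <- cur / sqrt(sum(cur^2))
  for (i in seq_len(max_iter)) {
    cl <- xyz_to_lonlat(cur)
    d <- haversine_km(cl[1], cl[2], pm[, 1], pm[, 2])
    hit <- d < 1e-9
    if (any(hit & w > 0)) {
      j <- which(hit & w > 0)[1]
      # current iterate coincides with a data point; nudge test via Weiszfeld rule
      d[hit] <- 1e-9
    }
    ww <- w / d
    nxt <- colSums(xyz * ww)
    nxt <- nxt / sqrt(sum(nxt^2))
    step <- sqrt(sum((nxt - cur)^2))
    cur <- nxt
    if (rad2deg(step) < tol) break
  }
  cl <- xyz_to_lonlat(cur)
  c(lon = unname(wrap_lon(cl[1])), lat = unname(cl[2]))
}

lonlat_to_xyz <- function(lon, lat) {
  lon <- deg2rad(lon); lat <- deg2rad(lat)
  cbind(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
}

xyz_to_lonlat <- function(v) {
  c(rad2deg(atan2(v[2], v[1])), rad2deg(asin(pmin(pmax(v[3], -1), 1))))
}

# Local azimuthal equidistant projection about (lon0, lat0): x east, y north, km.
project_aeqd <- function(lon, lat, lon0, lat0) {
  d <- haversine_km(lon0, lat0, lon, lat)
  b <- deg2rad(geosphere::bearing(c(lon0, lat0), cbind(lon, lat)))
  b[is.na(b)] <- 0
  cbind(x = d * sin(b), y = d * cos(b))
}

unproject_aeqd <- function(x, y, lon0, lat0) {
  d <- sqrt(x^2 + y^2)
  b <- rad2deg(atan2(x, y))
  p <- geosphere::destPoint(c(lon0, lat0), b, d * 1000, r = 6371008.8)
  colnames(p) <- c("lon", "lat")
  zero <- d < 1e-12
  p[zero, 1] <- lon0; p[zero, 2] <- lat0
  p
}

# Plate-carree local projection (lon/lat scaled to km about a reference lat).
project_platecarree <- function(lon, lat, lon0, lat0) {
  kmdeg <- 111.19493
  cbind(x = (lon - lon0) * kmdeg * cos(deg2rad(lat0)), y = (lat - lat0) * kmdeg)
}

unproject_platecarree <- function(x, y, lon0, lat0) {
  kmdeg <- 111.19493
  cbind(lon = lon0 + x / (kmdeg * cos(deg2rad(lat0))), lat = lat0 + y / kmdeg)
}
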