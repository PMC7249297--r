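#' Solar position (NOAA low-accuracy algorithm)
#'
#' Geometric solar elevation and azimuth for UTC times, following the NOAA
#' solar-calculator formulation (mean longitude/anomaly, equation of centre,
#' apparent longitude, corrected obliquity, equation of time). Atmospheric
#' refraction is deliberately not applied: in threshold geolocation the
#' calibrated sun-elevation angle absorbs refraction together with sensor and
#' shading effects.
#'
#' @param time POSIXct vector, UTC.
#' @param lon,lat position in decimal degrees (WGS84, lon positive east).
#' @return A tibble with columns `time`, `lon`, `lat`, `elevation`, `azimuth`
#'   (degrees), `declination` (degrees) and `eqtime` (minutes).
#' @examples
#' solar_position(as.POSIXct("2017-06-21 21:00", tz = "UTC"), 48.848, 69.138)
#' @export
solar_position <- function(time, lon, lat) {
  stopifnot(inherits(time, "POSIXct"))
  n <- max(length(time), length(lon), length(lat))
  time <- rep_len(time, n); lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  eph <- solar_ephemeris(time)
  min_day <- (as.numeric(time) %% 86400) / 60
  tst <- (min_day + eph$eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  dec_r <- deg2rad(eph$declination); lat_r <- deg2rad(lat); ha_r <- deg2rad(ha)
  sin_el <- sin(lat_r) * sin(dec_r) + cos(lat_r) * cos(dec_r) * cos(ha_r)
  sin_el <- pmin(pmax(sin_el, -1), 1)
  el <- asin(sin_el)
  cos_az <- (sin(dec_r) - sin(lat_r) * sin_el) / (cos(lat_r) * cos(el))
  cos_az[!is.finite(cos_az)] <- 1
  az <- rad2deg(acos(pmin(pmax(cos_az, -1), 1)))
  az <- ifelse(ha > 0, (az + 180) %% 360, (540 - az) %% 360)
  tibble::tibble(
    time = time, lon = lon, lat = lat,
    elevation = rad2deg(el), azimuth = az,
    declination = eph$declination, eqtime = eph$eqtime
  )
}

# Declination (deg) and equation of time (min) for POSIXct UTC times.
solar_ephemeris <- function(time) {
  jd <- as.numeric(time) / 86400 + 2440587.5
  t <- (jd - 2451545) / 36525
  L0 <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
  M <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  e <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  Mr <- deg2rad(M)
  C <- sin(Mr) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * Mr) * (0.019993 - 0.000101 * t) + sin(3 * Mr) * 0.000289
  omega <- deg2rad(125.04 - 1934.136 * t)
  lambda <- deg2rad(L0 + C - 0.00569 - 0.00478 * sin(omega))
  eps0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  eps <- deg2rad(eps0 + 0.00256 * cos(omega))
  dec <- rad2deg(asin(sin(eps) * sin(lambda)))
  y <- tan(eps / 2)^2
  L0r <- deg2rad(L0)
  eqtime <- 4 * rad2deg(
    y * sin(2 * L0r) - 2 * e * sin(Mr) + 4 * e * y * sin(Mr) * cos(2 * L0r) -
      0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr)
  )
  list(declination = dec, eqtime = eqtime)
}

#' Day length at the threshold sun-elevation angle
#'
#' Hours the sun spends above elevation `angle` at latitude `lat` when the
#' solar declination is `dec`, from the sunrise equation. Returns 24 during
#' polar day and 0 during polar night.
#'
#' @param lat latitude, degrees.
#' @param dec solar declination, degrees.
#' @param angle sun-elevation angle defining "day", degrees (negative below
#'   the horizon).
#' @return Numeric vector of hours in `[0, 24]`.
#' @export
day_length_hours <- function(lat, dec, angle) {
  lat_r <- deg2rad(lat); dec_r <- deg2rad(dec)
  cos_ha <- (sin(deg2rad(angle)) - sin(lat_r) * sin(dec_r)) / (cos(lat_r) * cos(dec_r))
  out <- rep(NA_real_, length(cos_ha))
  out[!is.na(cos_ha) & cos_ha <= -1] <- 24
  out[!is.na(cos_ha) & cos_ha >= 1] <- 0
  mid <- !is.na(cos_ha) & cos_ha > -1 & cos_ha < 1
  out[mid] <- 2 * rad2deg(acos(cos_ha[mid])) / 15
  out
}

#' Invert day length to latitude
#'
#' Closed-form inversion of the sunrise equation: given an observed day length
#' (time above the sun-elevation angle `angle`) on a date with declination
#' `dec`, solve `sin(dec) sin(lat) + cos(dec) cos(HA) cos(lat) = sin(angle)`
#' for latitude. The equation generically has two roots (a hemisphere alias
#' with identical day length); `lat_hint` selects the nearer one. Without a
#' hint, a pair of admissible roots more than 2 degrees apart is reported as
#' `NA` (ambiguous, the equinox degeneracy), as is any case with no admissible
#' root in `[-max_abs_lat, max_abs_lat]`.
#'
#' @param daylen_h observed day length, hours.
#' @param dec solar declination, degrees.
#' @param angle sun-elevation angle at the light threshold, degrees.
#' @param lat_hint optional latitude used to resolve the hemisphere alias.
#' @param max_abs_lat search bound, degrees (default 85).
#' @return Latitude in degrees, `NA` where undefined. Vectorised over all
#'   arguments.
#' @export
latitude_from_day_length <- function(daylen_h, dec, angle, lat_hint = NULL,
                                     max_abs_lat = 85) {
  n <- max(length(daylen_h), length(dec), length(angle),
           if (is.null(lat_hint)) 0 else length(lat_hint))
  daylen_h <- rep_len(daylen_h, n); dec <- rep_len(dec, n); angle <- rep_len(angle, n)
  hint <- if (is.null(lat_hint)) rep(NA_real_, n) else rep_len(lat_hint, n)
  ha <- daylen_h * 15 / 2
  A <- sin(deg2rad(dec))
  B <- cos(deg2rad(dec)) * cos(deg2rad(ha))
  C <- sin(deg2rad(angle))
  R <- sqrt(A^2 + B^2)
  s <- C / R
  phi <- rad2deg(atan2(B, A))
  as1 <- rad2deg(asin(pmin(pmax(s, -1), 1)))
  x1 <- wrap180(as1 - phi)
  x2 <- wrap180(180 - as1 - phi)
  solvable <- !is.na(s) & abs(s) <= 1
  v1 <- solvable & abs(x1) <= max_abs_lat
  v2 <- solvable & abs(x2) <= max_abs_lat
  out <- rep(NA_real_, n)
  only1 <- v1 & !v2; only2 <- v2 & !v1
  out[only1] <- x1[only1]
  out[only2] <- x2[only2]
  both <- v1 & v2
  if (any(both)) {
    has_hint <- both & !is.na(hint)
    pick1 <- abs(x1 - hint) <= abs(x2 - hint)
    out[has_hint] <- ifelse(pick1[has_hint], x1[has_hint], x2[has_hint])
    near <- both & is.na(hint) & abs(x1 - x2) <= 2
    out[near] <- (x1[near] + x2[near]) / 2
    # both roots admissible, far apart, no hint: ambiguous
  }
  out
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalize longitudes to [-180, 180)
#' @param lon longitudes in degrees.
#' @return Wrapped longitudes.
#' @export
wrap_lon <- function(lon) ((lon + 180) %% 360) - 180

wrap180 <- function(x) ((x + 180) %% 360) - 180
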