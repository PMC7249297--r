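# Independent ephemeris oracle (Astronomical Almanac / Michalsky-style
# formulation; a different algorithm lineage from the NOAA implementation
# in the package).
oracle_solar_elevation <- function(time, lon, lat) {
  jd <- as.numeric(time) / 86400 + 2440587.5
  d <- jd - 2451545
  g <- (357.529 + 0.98560028 * d) %% 360
  q <- (280.459 + 0.98564736 * d) %% 360
  L <- q + 1.915 * sin(g * pi / 180) + 0.020 * sin(2 * g * pi / 180)
  e <- 23.439 - 0.00000036 * d
  dec <- asin(sin(e * pi / 180) * sin(L * pi / 180))
  ra <- (atan2(cos(e * pi / 180) * sin(L * pi / 180), cos(L * pi / 180)) *
           180 / pi) %% 360
  gmst <- (18.697374558 + 24.06570982441908 * d) %% 24
  lmst <- (gmst * 15 + lon) %% 360
  ha <- (lmst - ra + 180) %% 360 - 180
  asin(sin(dec) * sin(lat * pi / 180) +
         cos(dec) * cos(lat * pi / 180) * cos(ha * pi / 180)) * 180 / pi
}

# Stationary single-stage scenario helper.
stationary_scenario <- function(lon, lat, start, end, label = "wintering",
                                bird_id = "T") {
  track_scenario(
    tibble::tibble(label = label, start = as.Date(start), end = as.Date(end),
                   lon = lon, lat = lat),
    bird_id = bird_id
  )
}

# Noise-free light for a stationary bird.
noisefree_light <- function(lon, lat, start, end, world = default_world(),
                            sun_angle = -3.5, seed = 1, step_sd_km = 0.001) {
  tr <- simulate_track(stationary_scenario(lon, lat, start, end), world,
                       seed = seed, step_sd_km = step_sd_km)
  simulate_light(tr, sun_angle = sun_angle,
                 shading = list(p_shade = 0, depth_meanlog = 0,
                                depth_sdlog = 0.7),
                 seed = seed + 1)
}

# Brute-force minute scan: first rising crossing of `angle` after `from`.
oracle_crossing <- function(lon, lat, date, angle, kind = c("rise", "set")) {
  kind <- match.arg(kind)
  mins <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + seq(0, 86399, 60)
  el <- solar_position(mins, lon, lat)$elevation
  n <- length(el)
  ix <- if (kind == "rise") {
    which(el[-n] <= angle & el[-1] > angle)
  } else {
    which(el[-n] >= angle & el[-1] < angle)
  }
  if (length(ix) == 0) return(NULL)
  mins[ix[1]]
}
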