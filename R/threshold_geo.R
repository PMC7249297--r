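#' Position from one twilight pair (threshold method)
#'
#' Longitude comes from the pair midpoint: the midpoint of a sunrise-sunset
#' pair is local solar noon (for a sunset-sunrise night pair, local solar
#' midnight), which fixes longitude at 15 degrees per hour of offset from
#' UTC after the equation-of-time correction. Latitude is the solution of
#' the sunrise equation whose day length at the calibrated sun-elevation
#' angle matches the observed day (or night) length; see
#' [latitude_from_day_length()] for the closed form, hemisphere-alias
#' handling and the equinox degeneracy. Near the equinoxes the day length
#' carries no latitude information and `lat_flag` is set to
#' `equinox_undefined` with `lat = NA` (never a placeholder value); for a
#' polar-day pair, `lat_flag` is `polar_undefined` and longitude is
#' recovered from the estimated midnight.
#'
#' @param t1,t2 POSIXct times of the two twilights (order as observed).
#' @param kind1,kind2 `"sunrise"`/`"sunset"` of each twilight.
#' @param angle calibrated sun-elevation angle, degrees.
#' @param lat_hint optional latitude to resolve the hemisphere alias.
#' @param polar logical; TRUE for a polar-day midnight pair.
#' @return One-row tibble: `time` (midpoint), `lon`, `lat`, `lat_flag`
#'   (`ok`/`equinox_undefined`/`polar_undefined`), `type` (`day`/`night`/
#'   `polar`).
#' @export
position_from_pair <- function(t1, t2, kind1, kind2, angle, lat_hint = NULL,
                               polar = FALSE) {
  if (as.numeric(t2) - as.numeric(t1) > 24 * 3600) {
    stop("pairing error: twilights more than 24 h apart", call. = FALSE)
  }
  mid <- t1 + (as.numeric(t2) - as.numeric(t1)) / 2
  eph <- solar_ephemeris(mid)
  min_day <- (as.numeric(mid) %% 86400) / 60
  if (polar) {
    lon <- wrap_lon(-(min_day + eph$eqtime) / 4)
    return(tibble::tibble(time = mid, lon = lon, lat = NA_real_,
                          lat_flag = "polar_undefined", type = "polar"))
  }
  if (kind1 == "sunrise" && kind2 == "sunset") {
    type <- "day"
    lon <- wrap_lon((720 - min_day - eph$eqtime) / 4)
    daylen <- (as.numeric(t2) - as.numeric(t1)) / 3600
  } else if (kind1 == "sunset" && kind2 == "sunrise") {
    type <- "night"
    lon <- wrap_lon(-(min_day + eph$eqtime) / 4)
    daylen <- 24 - (as.numeric(t2) - as.numeric(t1)) / 3600
  } else {
    stop("pairing error: need one sunrise and one sunset", call. = FALSE)
  }
  lat <- latitude_from_day_length(daylen, eph$declination, angle,
                                  lat_hint = lat_hint)
  flag <- "ok"
  if (is.na(lat)) {
    flag <- "equinox_undefined"
  } else {
    # residual check: modelled day length at the solution must match
    mod <- day_length_hours(lat, eph$declination, angle)
    if (is.na(mod) || abs(mod - daylen) * 60 > 10) {
      lat <- NA_real_
      flag <- "equinox_undefined"
    }
  }
  tibble::tibble(time = mid, lon = lon, lat = lat, lat_flag = flag, type = type)
}

#' Positions for a whole validated twilight record
#'
#' Pairs every consecutive pair of validated twilights closer than 24 h
#' (sunrise-sunset day pairs and sunset-sunrise night pairs, at most two
#' positions per day) and applies the threshold method with one calibrated
#' angle. Polar-day midnight events yield longitude-only positions.
#'
#' @param twilights validated events from [validate_twilights()].
#' @param angle calibrated sun-elevation angle, degrees.
#' @param lat_hint optional latitude (e.g. the deployment site) used to
#'   resolve the hemisphere alias of the day-length inversion.
#' @param method label stored in the `method` column.
#' @return Tibble: `pair_id`, `time`, `date`, `lon`, `lat`, `lat_flag`,
#'   `type`, `method`.
#' @export
positions_from_twilights <- function(twilights, angle, lat_hint = NULL,
                                     method = "threshold") {
  tw <- tibble::as_tibble(twilights)
  if (nrow(tw) < 2) {
    return(tibble::tibble(pair_id = integer(), time = as.POSIXct(character(), tz = "UTC"),
                          date = as.Date(character()), lon = numeric(), lat = numeric(),
                          lat_flag = character(), type = character(), method = character()))
  }
  pr <- twilight_pairs(tw)
  lat <- latitude_from_day_length(pr$daylen, pr$declination, angle,
                                  lat_hint = lat_hint)
  mod <- day_length_hours(lat, pr$declination, angle)
  bad <- !is.na(lat) & (is.na(mod) | abs(mod - pr$daylen) * 60 > 10)
  lat[bad] <- NA_real_
  flag <- ifelse(pr$type == "polar", "polar_undefined",
                 ifelse(is.na(lat), "equinox_undefined", "ok"))
  lat[pr$type == "polar"] <- NA_real_
  tibble::tibble(
    pair_id = seq_len(nrow(pr)), time = pr$mid, date = as.Date(pr$mid),
    lon = pr$lon, lat = lat, lat_flag = flag, type = pr$type, method = method
  )
}

# Consecutive-twilight pair table shared by the threshold and particle models:
# midpoint time/longitude, day length at the threshold, declination.
twilight_pairs <- function(tw) {
  tw <- tw[order(tw$time), ]
  n <- nrow(tw)
  first <- seq_len(n - 1)
  gap <- as.numeric(tw$time[first + 1]) - as.numeric(tw$time[first])
  polar_pair <- tw$polar_day[first] & tw$polar_day[first + 1] & gap < 60
  normal <- !tw$polar_day[first] & !tw$polar_day[first + 1] &
    tw$kind[first] != tw$kind[first + 1] & gap <= 24 * 3600
  use <- which(polar_pair | normal)
  mid <- tw$time[use] + gap[use] / 2
  eph <- solar_ephemeris(mid)
  min_day <- (as.numeric(mid) %% 86400) / 60
  type <- ifelse(polar_pair[use], "polar",
                 ifelse(tw$kind[use] == "sunrise", "day", "night"))
  lon <- ifelse(type == "day",
                (720 - min_day - eph$eqtime) / 4,
                -(min_day + eph$eqtime) / 4)
  daylen <- ifelse(type == "day", gap[use] / 3600,
                   ifelse(type == "night", 24 - gap[use] / 3600, NA_real_))
  tibble::tibble(
    t1 = tw$time[use], t2 = tw$time[use + 1], mid = mid,
    type = type, lon = wrap_lon(lon), daylen = daylen,
    declination = eph$declination, eqtime = eph$eqtime
  )
}

#' Known-site (rooftop) calibration
#'
#' The sun-elevation angle of a logger recorded at a known location: detect
#' twilights in the calibration light series and take the median geometric
#' solar elevation at the crossing times, evaluated at the known site.
#'
#' @param light calibration light series (tibble `time`, `light`).
#' @param lon,lat the known calibration site, degrees.
#' @param threshold light threshold (must match the analysis threshold).
#' @param min_days minimum number of distinct twilight days (default 7).
#' @return A `sun_calibration` object (method, angle, diagnostics).
#' @export
calibrate_known_site <- function(light, lon, lat, threshold = 2.5, min_days = 7) {
  ev <- detect_twilights(light, threshold = threshold, site_lon = lon)
  ev <- ev[ev$quality == "ok" & !ev$polar_day, ]
  if (length(unique(as.Date(ev$time))) < min_days) {
    stop("calibration error: need twilights on at least ", min_days,
         " days at the known site", call. = FALSE)
  }
  el <- solar_position(ev$time, lon, lat)$elevation
  new_sun_calibration(
    method = "known_site",
    angle = stats::median(el),
    window = range(as.Date(ev$time)),
    diagnostics = tibble::tibble(time = ev$time, kind = ev$kind, elevation = el)
  )
}

#' Hill-Ekstrom calibration
#'
#' Chooses the sun-elevation angle that minimises the variance of the
#' latitude series over a known stationary period (classically a wintering
#' site): at the true angle the day-length-derived latitudes are flattest,
#' while any other angle imprints the seasonal declination trend on them.
#' Returns the full variance-versus-angle profile as a diagnostic.
#'
#' @param twilights validated twilight events covering the stationary window.
#' @param window Date vector `c(start, end)` of the stationary period;
#'   must span at least `min_days` and should avoid equinoxes by ~15 days.
#' @param angle_grid candidate angles, degrees (default -10 to 0 by 0.25).
#' @param lat_hint optional hemisphere hint for the latitude inversion.
#' @param min_days minimum window length in days (default 30).
#' @return A `sun_calibration` with the selected angle and profile.
#' @export
calibrate_hill_ekstrom <- function(twilights, window,
                                   angle_grid = seq(-10, 0, by = 0.25),
                                   lat_hint = NULL, min_days = 30) {
  window <- as.Date(window)
  if (as.numeric(diff(window)) < min_days) {
    stop("calibration error: stationary window shorter than ", min_days, " days",
         call. = FALSE)
  }
  for (yr in unique(format(seq(window[1], window[2], by = "day"), "%Y"))) {
    eqd <- as.Date(paste0(yr, c("-03-20", "-09-22")))
    near <- eqd[eqd >= window[1] - 15 & eqd <= window[2] + 15]
    if (length(near) > 0) {
      warning("Hill-Ekstrom window lies within 15 days of an equinox (",
              paste(near, collapse = ", "), "); latitudes may be unstable")
      break
    }
  }
  tw <- tibble::as_tibble(twilights)
  tw <- tw[as.Date(tw$time) >= window[1] & as.Date(tw$time) <= window[2], ]
  profile <- purrr::map_dfr(angle_grid, function(a) {
    pos <- positions_from_twilights(tw, angle = a, lat_hint = lat_hint)
    lat <- pos$lat[pos$lat_flag == "ok"]
    tibble::tibble(angle = a,
                   lat_var = if (length(lat) >= 5) stats::var(lat) else NA_real_,
                   n_defined = length(lat))
  })
  if (all(is.na(profile$lat_var))) {
    stop("calibration error: no candidate angle yields defined latitudes",
         call. = FALSE)
  }
  best <- profile$angle[which.min(profile$lat_var)]
  new_sun_calibration(
    method = "hill_ekstrom", angle = best, window = window,
    diagnostics = profile
  )
}

new_sun_calibration <- function(method, angle, window, diagnostics) {
  stopifnot(is.finite(angle))
  structure(list(method = method, angle = angle, window = window,
                 diagnostics = diagnostics),
            class = "sun_calibration")
}

#' @export
print.sun_calibration <- function(x, ...) {
  cat("<sun_calibration>", x$method, "angle:", round(x$angle, 2), "deg\n")
  invisible(x)
}
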