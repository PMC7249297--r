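#' Construct a synthetic world model
#'
#' The world supplies the environmental surfaces the probabilistic track model
#' and the simulator need: a water-type classification (freshwater/land,
#' brackish sea, open sea), a sea-surface-temperature field and an ice mask.
#' Regions are axis-aligned lon/lat rectangles checked in order, which keeps
#' every surface exactly computable in tests. Real coastlines are out of
#' scope; the default world is an abstract Barents/Baltic-like rectangle.
#'
#' @param bbox named numeric `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param regions tibble with columns `name`, `class`
#'   (`land_fresh`/`brackish_sea`/`open_sea`), `lon_min`, `lon_max`,
#'   `lat_min`, `lat_max`; the first matching row wins, unmatched cells are
#'   `open_sea`.
#' @param sst_fun function `(lon, lat, date) -> degC`.
#' @param ice_fun function `(lon, lat, date) -> logical`.
#' @return An object of class `duck_world` with functions `water_class`,
#'   `sst`, `ice` plus the region table.
#' @export
world_model <- function(bbox, regions, sst_fun, ice_fun) {
  stopifnot(length(bbox) == 4, is.function(sst_fun), is.function(ice_fun))
  regions <- tibble::as_tibble(regions)
  need <- c("name", "class", "lon_min", "lon_max", "lat_min", "lat_max")
  if (!all(need %in% names(regions))) {
    stop("regions must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(regions$class %in% c("land_fresh", "brackish_sea", "open_sea"))) {
    stop("unknown water class in regions", call. = FALSE)
  }
  water_class <- function(lon, lat) {
    lon <- wrap_lon(lon)
    out <- rep("open_sea", length(lon))
    unset <- rep(TRUE, length(lon))
    for (i in seq_len(nrow(regions))) {
      r <- regions[i, ]
      hit <- unset & lon >= r$lon_min & lon <= r$lon_max &
        lat >= r$lat_min & lat <= r$lat_max
      out[hit] <- r$class
      unset <- unset & !hit
    }
    out
  }
  structure(
    list(bbox = bbox, regions = regions, water_class = water_class,
         sst = sst_fun, ice = ice_fun),
    class = "duck_world"
  )
}

#' Default synthetic world (Barents/Baltic-like)
#'
#' An abstract rectangle from the eastern North Atlantic to the Kara-side
#' Arctic holding: a tundra breeding region with freshwater lakes around
#' 69.1N 48.8E; a brackish "Baltic-like" basin (lon 14-30, lat 54-61.5) with
#' open sea directly north of it; a marine "White-Sea-like" embayment spanning
#' lon 33.9-41.6 (the longitudinal band used to classify White Sea
#' stopovers); and continental land masses to the south and east. SST follows
#' a smooth north-south gradient with a latitude-dependent seasonal sinusoid
#' whose closed form is documented so tests can recompute it:
#' `sst = max(m + a cos(2 pi (doy - 215) / 365.25), -1)` with
#' `m = 8 - 0.35 (lat - 55)` and `a = max(7 - 0.25 (lat - 55), 0)`. In winter
#' the north-south SST contrast nearly vanishes (as it does between the real
#' Baltic and the subarctic seas), so water type, not temperature, is what
#' separates the basins. Ice covers latitudes above 71.5N from December to
#' April.
#'
#' @return A `duck_world`.
#' @export
default_world <- function() {
  regions <- tibble::tribble(
    ~name, ~class, ~lon_min, ~lon_max, ~lat_min, ~lat_max,
    "white_sea",      "open_sea",     33.9, 41.6, 63.5, 66.5,
    "tundra_lakes",   "land_fresh",   46,   52,   68.3, 70.0,
    "south_land",     "land_fresh",   -5,   70,   50,   54,
    "scandinavia",    "land_fresh",    5,   14,   54,   71,
    "mainland_east",  "land_fresh",   30,   70,   54,   67,
    "baltic",         "brackish_sea", 14,   30,   54,   61.5
  )
  world_model(
    bbox = c(lon_min = -5, lon_max = 70, lat_min = 50, lat_max = 78),
    regions = regions,
    sst_fun = synthetic_sst,
    ice_fun = function(lon, lat, date) {
      m <- as.integer(format(as.Date(date), "%m"))
      lat > 71.5 & m %in% c(12, 1, 2, 3, 4)
    }
  )
}

#' Closed-form synthetic SST field
#'
#' @param lon,lat coordinates (degrees; the field is zonally uniform).
#' @param date Date or POSIXct.
#' @return SST in degrees C, floored at -1 (freezing seawater).
#' @export
synthetic_sst <- function(lon, lat, date) {
  doy <- as.numeric(format(as.Date(date), "%j"))
  m <- 8 - 0.35 * (lat - 55)
  a <- pmax(7 - 0.25 * (lat - 55), 0)
  pmax(m + a * cos(2 * pi * (doy - 215) / 365.25), -1)
}

#' Two-basin test world
#'
#' A minimal world for isolating the conductivity extension of the track
#' model: a brackish basin (lat 54-58) directly below an open-sea basin
#' (lat 58-62) at the same longitudes, land everywhere else, spatially and
#' seasonally constant SST (so temperature carries no information), no ice.
#' Only the water-type term can tell the basins apart.
#'
#' @param sst_const constant SST in degC (default 4).
#' @return A `duck_world`.
#' @export
two_basin_world <- function(sst_const = 4) {
  regions <- tibble::tribble(
    ~name, ~class, ~lon_min, ~lon_max, ~lat_min, ~lat_max,
    "brackish_basin", "brackish_sea", 10, 30, 54, 58,
    "marine_basin",   "open_sea",     10, 30, 58, 62,
    "land",           "land_fresh",  -30, 60, 30, 80
  )
  world_model(
    bbox = c(lon_min = -30, lon_max = 60, lat_min = 30, lat_max = 80),
    regions = regions,
    sst_fun = function(lon, lat, date) rep(sst_const, max(length(lon), length(lat))),
    ice_fun = function(lon, lat, date) rep(FALSE, max(length(lon), length(lat)))
  )
}
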