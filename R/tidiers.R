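#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sun-elevation calibration
#'
#' For a Hill-Ekstrom calibration, the variance-versus-angle profile; for a
#' known-site calibration, the per-crossing solar elevations.
#'
#' @param x a `sun_calibration`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy sun_calibration
#' @export
tidy.sun_calibration <- function(x, ...) {
  tibble::as_tibble(x$diagnostics)
}

#' @rdname tidy.sun_calibration
#' @method glance sun_calibration
#' @export
glance.sun_calibration <- function(x, ...) {
  tibble::tibble(method = x$method, angle = x$angle,
                 window_start = x$window[1], window_end = x$window[2])
}

#' Tidy a probabilistic track fit
#'
#' The per-twilight-pair median track (position, chosen sun-elevation angle,
#' effective sample size, logger water class).
#'
#' @param x a `duck_track`.
#' @param ... unused.
#' @return A tibble with one row per twilight pair.
#' @method tidy duck_track
#' @export
tidy.duck_track <- function(x, ...) x$track

#' @rdname tidy.duck_track
#' @method glance duck_track
#' @export
glance.duck_track <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$track), n_particles = x$n_particles,
    conductivity = x$conductivity, mean_ess = mean(x$track$ess),
    min_ess = min(x$track$ess), seed = x$seed
  )
}

#' Tidy a stage segmentation
#'
#' @param x a `stage_segmentation`.
#' @param ... unused.
#' @return The interval tibble (`label`, `start`, `end`, `n_days`,
#'   `mean_lon`, `sd_lon`) with the bird id attached.
#' @method tidy stage_segmentation
#' @export
tidy.stage_segmentation <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(bird_id = x$bird_id), x$intervals)
}

#' @rdname tidy.stage_segmentation
#' @method glance stage_segmentation
#' @export
glance.stage_segmentation <- function(x, ...) {
  tibble::tibble(
    bird_id = x$bird_id, n_stages = nrow(x$intervals),
    n_stopovers = if (is.null(x$stopovers)) NA_integer_ else nrow(x$stopovers),
    deployment_days = as.numeric(max(x$intervals$end) - min(x$intervals$start))
  )
}

#' Tidy a utilization distribution
#'
#' @param x a `duck_ud`.
#' @param ... unused.
#' @return Tibble of grid cells: `lon`, `lat`, `x`, `y` (km), `density`,
#'   `mass`.
#' @method tidy duck_ud
#' @export
tidy.duck_ud <- function(x, ...) {
  tibble::tibble(
    lon = as.vector(x$grid_lon), lat = as.vector(x$grid_lat),
    x = rep(x$x, times = length(x$y)), y = rep(x$y, each = length(x$x)),
    density = as.vector(x$z), mass = as.vector(x$z) * x$cell_area
  )
}

#' @rdname tidy.duck_ud
#' @method glance duck_ud
#' @export
glance.duck_ud <- function(x, ...) {
  tibble::tibble(n = x$n, h_km = x$h, grid_cells = length(x$x),
                 projection = x$projection,
                 total_mass = sum(x$z) * x$cell_area)
}
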