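#' Kernel utilization distribution
#'
#' Bivariate normal kernel density of a point set on a projected plane,
#' with the classical "ad hoc" reference bandwidth
#' `h = sqrt((var(x) + var(y)) / 2) * n^(-1/6)` (one isotropic h for both
#' axes) and a square grid of `grid_cells` cells per axis over the point
#' bounding box padded by 3h. Points are projected either through a local
#' azimuthal equidistant projection about their centroid (default; treats
#' distances faithfully at these latitudes) or plate carree (degrees scaled
#' at the centroid latitude, mirroring a naive lon/lat computation); the
#' resulting cell masses are normalised to sum to one.
#'
#' @param points data frame with `lon`, `lat` columns.
#' @param grid_cells cells per axis (default 100).
#' @param bandwidth `"adhoc"` or a numeric kernel SD in km.
#' @param projection `"aeqd"` or `"platecarree"`.
#' @return A `duck_ud`: grid coordinates (km and lon/lat), density matrix
#'   (integrates to 1 over the grid), bandwidth, cell area, projection
#'   metadata.
#' @export
kernel_ud <- function(points, grid_cells = 100, bandwidth = "adhoc",
                      projection = c("aeqd", "platecarree")) {
  projection <- match.arg(projection)
  pts <- tibble::as_tibble(points)[, c("lon", "lat")]
  pts <- pts[stats::complete.cases(pts), ]
  n <- nrow(pts)
  if (n < 5) stop("kernel_ud() needs at least 5 points", call. = FALSE)
  lon0 <- mean(pts$lon); lat0 <- mean(pts$lat)
  xy <- if (projection == "aeqd") {
    project_aeqd(pts$lon, pts$lat, lon0, lat0)
  } else {
    project_platecarree(pts$lon, pts$lat, lon0, lat0)
  }
  if (identical(bandwidth, "adhoc")) {
    h <- sqrt((stats::var(xy[, 1]) + stats::var(xy[, 2])) / 2) * n^(-1 / 6)
  } else {
    h <- as.numeric(bandwidth)
  }
  if (!is.finite(h) || h <= 0) {
    stop("degenerate bandwidth (all points identical?); supply a numeric ",
         "bandwidth in km", call. = FALSE)
  }
  pad <- 3 * h
  gx <- seq(min(xy[, 1]) - pad, max(xy[, 1]) + pad, length.out = grid_cells)
  gy <- seq(min(xy[, 2]) - pad, max(xy[, 2]) + pad, length.out = grid_cells)
  # separable Gaussian kernels: density = Kx' Ky / n
  Kx <- stats::dnorm(outer(xy[, 1], gx, "-") / h) / h
  Ky <- stats::dnorm(outer(xy[, 2], gy, "-") / h) / h
  z <- crossprod(Kx, Ky) / n   # grid_cells x grid_cells, rows = x
  cell_area <- diff(gx)[1] * diff(gy)[1]
  z <- z / (sum(z) * cell_area) # normalise mass over the grid
  gll <- expand.grid(x = gx, y = gy)
  back <- if (projection == "aeqd") {
    unproject_aeqd(gll$x, gll$y, lon0, lat0)
  } else {
    unproject_platecarree(gll$x, gll$y, lon0, lat0)
  }
  structure(
    list(x = gx, y = gy, z = z, h = h, n = n, cell_area = cell_area,
         lon0 = lon0, lat0 = lat0, projection = projection,
         grid_lon = matrix(back[, 1], grid_cells, grid_cells),
         grid_lat = matrix(back[, 2], grid_cells, grid_cells)),
    class = "duck_ud"
  )
}

#' @export
print.duck_ud <- function(x, ...) {
  cat("<duck_ud>", x$n, "points,", length(x$x), "x", length(x$y),
      "grid, h =", round(x$h, 1), "km (", x$projection, ")\n")
  invisible(x)
}

# Density threshold whose highest-density region holds `level`% of mass.
ud_threshold <- function(ud, level) {
  m <- as.vector(ud$z) * ud$cell_area
  o <- order(m, decreasing = TRUE)
  cum <- cumsum(m[o])
  k <- which(cum >= level / 100)[1]
  as.vector(ud$z)[o[k]]
}

#' Utilization contour polygons
#'
#' The smallest density-threshold region containing `level` percent of the
#' total mass, returned as polygon rings in geographic coordinates. Two
#' well-separated clusters legitimately yield several disjoint rings at low
#' levels; all are returned (`piece` indexes them).
#'
#' @param ud a `duck_ud`.
#' @param level percentage of mass in (0, 100).
#' @return Tibble: `level`, `piece`, `lon`, `lat`, with attributes
#'   `threshold` (density cut) and `mass` (grid mass actually enclosed).
#' @export
ud_contour <- function(ud, level) {
  stopifnot(inherits(ud, "duck_ud"), level > 0, level < 100)
  thr <- ud_threshold(ud, level)
  cl <- grDevices::contourLines(ud$x, ud$y, ud$z, levels = thr)
  if (length(cl) == 0) {
    return(structure(tibble::tibble(level = numeric(), piece = integer(),
                                    lon = numeric(), lat = numeric()),
                     threshold = thr, mass = NA_real_))
  }
  out <- purrr::map_dfr(seq_along(cl), function(k) {
    p <- if (ud$projection == "aeqd") {
      unproject_aeqd(cl[[k]]$x, cl[[k]]$y, ud$lon0, ud$lat0)
    } else {
      unproject_platecarree(cl[[k]]$x, cl[[k]]$y, ud$lon0, ud$lat0)
    }
    tibble::tibble(level = level, piece = k, lon = p[, 1], lat = p[, 2])
  })
  mass <- sum((as.vector(ud$z) * ud$cell_area)[as.vector(ud$z) >= thr])
  structure(out, threshold = thr, mass = mass)
}

# GeoJSON FeatureCollection of contour polygons for a set of levels.
ud_contours_geojson <- function(ud, levels = c(25, 50, 75)) {
  feats <- list()
  for (lv in levels) {
    ct <- ud_contour(ud, lv)
    for (pc in unique(ct$piece)) {
      ring <- ct[ct$piece == pc, c("lon", "lat")]
      if (nrow(ring) < 3) next
      if (ring$lon[1] != ring$lon[nrow(ring)] ||
          ring$lat[1] != ring$lat[nrow(ring)]) {
        ring <- rbind(ring, ring[1, ])
      }
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = list(level = lv),
        geometry = list(
          type = "Polygon",
          coordinates = list(unname(as.matrix(ring)))
        )
      )
    }
  }
  as.character(jsonlite::toJSON(
    list(type = "FeatureCollection", features = feats),
    auto_unbox = TRUE, digits = 6
  ))
}
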