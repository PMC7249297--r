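#' Plot a utilization distribution
#'
#' Filled utilization contours (25/50/75% by default) in geographic
#' coordinates, darkest for the core area.
#'
#' @param object a `duck_ud`.
#' @param levels contour levels in percent.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot duck_ud
#' @export
autoplot.duck_ud <- function(object, levels = c(25, 50, 75), ...) {
  ct <- purrr::map_dfr(sort(levels, decreasing = TRUE),
                       function(lv) ud_contour(object, lv))
  ct$group <- interaction(ct$level, ct$piece)
  ggplot2::ggplot(ct, ggplot2::aes(.data$lon, .data$lat, group = .data$group,
                                   fill = factor(.data$level))) +
    ggplot2::geom_polygon(alpha = 0.8, colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c("#ffd92f", "#e34a33", "#7f0000"),
                               breaks = sort(levels),
                               name = "UD level (%)") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}

#' Plot a probabilistic track
#'
#' Median path coloured by date, with the tagging location marked.
#'
#' @param object a `duck_track`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot duck_track
#' @export
autoplot.duck_track <- function(object, ...) {
  tr <- object$track
  ggplot2::ggplot(tr, ggplot2::aes(.data$lon, .data$lat, colour = .data$date)) +
    ggplot2::geom_path(linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::annotate("point", x = object$start["lon"], y = object$start["lat"],
                      shape = 4, size = 3, colour = "black") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude", colour = NULL)
}

#' Plot an annual-cycle segmentation
#'
#' Daily longitude coloured by assigned stage, with stopovers outlined.
#'
#' @param object a `stage_segmentation`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot stage_segmentation
#' @export
autoplot.stage_segmentation <- function(object, ...) {
  d <- object$daily
  iv <- object$intervals
  d$stage <- NA_character_
  for (j in seq_len(nrow(iv))) {
    d$stage[d$date >= iv$start[j] & d$date < iv$end[j]] <- iv$label[j]
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$date, .data$lon,
                                       colour = .data$stage)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = NULL, y = "Longitude (deg E)", colour = "Stage")
  so <- object$stopovers
  if (!is.null(so) && nrow(so) > 0) {
    p <- p + ggplot2::annotate("rect", xmin = so$start, xmax = so$end,
                               ymin = so$mean_lon - 2, ymax = so$mean_lon + 2,
                               alpha = 0, colour = "black", linetype = 2)
  }
  p
}

#' Plot a Hill-Ekstrom calibration profile
#'
#' Latitude variance against candidate sun-elevation angle, with the
#' selected angle marked.
#'
#' @param object a `sun_calibration`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot sun_calibration
#' @export
autoplot.sun_calibration <- function(object, ...) {
  if (object$method == "hill_ekstrom") {
    ggplot2::ggplot(object$diagnostics,
                    ggplot2::aes(.data$angle, .data$lat_var)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_vline(xintercept = object$angle, linetype = 2) +
      ggplot2::labs(x = "Sun-elevation angle (deg)",
                    y = "Latitude variance (deg^2)")
  } else {
    ggplot2::ggplot(object$diagnostics,
                    ggplot2::aes(.data$time, .data$elevation,
                                 colour = .data$kind)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_hline(yintercept = object$angle, linetype = 2) +
      ggplot2::labs(x = NULL, y = "Solar elevation at crossing (deg)",
                    colour = NULL)
  }
}
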