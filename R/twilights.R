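#' Detect sunrise and sunset events from a light series
#'
#' Twilights are linearly interpolated crossings of the light threshold:
#' rising crossings become sunrises, falling crossings sunsets. Crossings are
#' never interpolated across recording gaps. Quality control mimics manual
#' "unequivocal assignment" screening automatically: when several crossings
#' of the same kind fall within 4 h of each other (shading dips), the
#' earliest sunset / latest sunrise of the cluster is kept and the rest are
#' flagged `ambiguous`. Days on which the light never drops below the
#' threshold are polar days: a sunrise and a sunset are both emitted at the
#' estimated local solar midnight, computed from the median pair longitude of
#' the 7 days preceding the polar run (deployment-site longitude when no
#' prior longitude exists).
#'
#' @param light tibble with `time` (POSIXct UTC) and `light`.
#' @param threshold light threshold on the logger scale (default 2.5).
#' @param site_lon deployment-site longitude used as the polar-day fallback.
#' @param qc_window_h same-kind crossings closer than this are ambiguous
#'   (default 4 h).
#' @param pooling_window_min width in minutes of the logger's max-pooling
#'   window (each stored sample is the maximum over `[t, t + w)` minutes).
#'   Because the stored maximum of a rising light curve equals its last
#'   minute, rising crossings are systematically early by `w - 1` minutes
#'   and are shifted accordingly; falling crossings are unbiased. Set to 1
#'   for instantaneously sampled light.
#' @return Tibble with `time`, `kind` (`sunrise`/`sunset`), `quality`
#'   (`ok`/`ambiguous`), `polar_day`.
#' @export
detect_twilights <- function(light, threshold = 2.5, site_lon = NULL,
                             qc_window_h = 4, pooling_window_min = 5) {
  light <- tibble::as_tibble(light)
  if (nrow(light) == 0) stop("light series is empty", call. = FALSE)
  lt <- light$light
  tm <- light$time
  date <- as.Date(tm)
  # calibration sanity: threshold must be inside the observed range on most days
  rng <- dplyr::summarise(dplyr::group_by(tibble::tibble(date, lt), date),
                          lo = min(lt), hi = max(lt), .groups = "drop")
  # days whose light never reaches the threshold indicate a mis-set
  # threshold; days that never fall below it are legitimate polar days
  dark_frac <- mean(threshold > rng$hi)
  if (dark_frac > 0.5) {
    stop("calibration error: threshold ", threshold,
         " lies above the observed light range on ",
         round(100 * dark_frac), "% of days", call. = FALSE)
  }

  n <- length(lt)
  dt <- diff(as.numeric(tm))
  contig <- dt == 300
  below <- lt < threshold
  rise <- which(contig & below[-n] & !below[-1])
  fall <- which(contig & !below[-n] & below[-1])
  interp <- function(i) {
    tm[i] + 300 * (threshold - lt[i]) / (lt[i + 1] - lt[i])
  }
  ev <- tibble::tibble(
    time = c(interp(rise) + (pooling_window_min - 1) * 60, interp(fall)),
    kind = c(rep("sunrise", length(rise)), rep("sunset", length(fall)))
  )
  ev <- ev[order(ev$time), ]
  ev$quality <- "ok"
  ev$polar_day <- FALSE

  # shading dips: adjacent opposite-kind crossings implausibly close
  # (a < 1 h "night" or "day") are artifacts; flag both
  if (nrow(ev) > 1) {
    repeat {
      ok_ix <- which(ev$quality == "ok")
      if (length(ok_ix) < 2) break
      gaps <- diff(as.numeric(ev$time[ok_ix]))
      opp <- ev$kind[ok_ix[-length(ok_ix)]] != ev$kind[ok_ix[-1]]
      hit <- which(opp & gaps < 3600)
      if (length(hit) == 0) break
      ev$quality[ok_ix[c(hit[1], hit[1] + 1)]] <- "ambiguous"
    }
  }

  # same-kind clusters within the QC window
  for (k in c("sunrise", "sunset")) {
    ix <- which(ev$kind == k & ev$quality == "ok")
    if (length(ix) < 2) next
    gap <- diff(as.numeric(ev$time[ix]))
    newgrp <- c(TRUE, gap > qc_window_h * 3600)
    grp <- cumsum(newgrp)
    for (g in unique(grp[duplicated(grp)])) {
      members <- ix[grp == g]
      keep <- if (k == "sunset") members[1] else members[length(members)]
      ev$quality[setdiff(members, keep)] <- "ambiguous"
    }
  }

  # polar days: no crossing and light always above threshold. The midnight
  # is estimated from the light curve itself where it shows a usable dip
  # (the sun is lowest at local solar midnight even under 24-h daylight);
  # otherwise from the median pair longitude of the preceding week, falling
  # back to the deployment-site longitude.
  days <- unique(date)
  cross_dates <- unique(as.Date(ev$time))
  lon_pairs <- twilight_pair_lons(ev[ev$quality == "ok", ])
  polar <- list()
  run_lon <- NA_real_
  prev_polar <- FALSE
  tnum <- as.numeric(tm)
  for (d in as.list(days)) {
    sel <- date == d
    is_polar <- !(d %in% cross_dates) && all(lt[sel] >= threshold) && sum(sel) >= 144
    if (is_polar) {
      if (!prev_polar) {
        recent <- lon_pairs$lon[lon_pairs$date >= d - 7 & lon_pairs$date < d]
        if (length(recent) == 0) recent <- utils::tail(lon_pairs$lon[lon_pairs$date < d], 3)
        run_lon <- if (length(recent) > 0) stats::median(recent)
        else if (!is.null(site_lon)) site_lon
        else NA_real_
        if (is.na(run_lon)) {
          warning("no longitude available for polar-day midnight; using 0")
          run_lon <- 0
        }
      }
      noon <- as.numeric(as.POSIXct(paste(d, "12:00:00"), tz = "UTC"))
      eq <- solar_ephemeris(as.POSIXct(noon, tz = "UTC",
                                       origin = "1970-01-01"))$eqtime
      # light-minimum midnight over the noon-to-noon window
      win <- which(tnum >= noon & tnum < noon + 86400)
      midnight <- NULL
      if (length(win) >= 276) {
        sm <- stats::filter(lt[win], rep(1 / 25, 25), sides = 2)
        if (sum(!is.na(sm)) > 50 && diff(range(sm, na.rm = TRUE)) >= 2) {
          # integer light flattens the dip into a plateau; use its centre,
          # and distrust minima touching the window edges
          low <- which(sm <= min(sm, na.rm = TRUE) + 0.2)
          j <- round(stats::median(low))
          if (j > 12 && j < length(win) - 12) midnight <- tm[win[j]]
        }
      }
      if (is.null(midnight)) {
        m <- (-4 * run_lon - eq) %% 1440
        midnight <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC") + m * 60
      } else {
        # carry the dip-derived longitude forward for truncated days
        mm <- (as.numeric(midnight) %% 86400) / 60
        run_lon <- wrap_lon(-(mm + eq) / 4)
      }
      polar[[length(polar) + 1]] <- tibble::tibble(
        time = rep(midnight, 2), kind = c("sunrise", "sunset"),
        quality = "ok", polar_day = TRUE
      )
    }
    prev_polar <- is_polar
  }
  if (length(polar) > 0) ev <- dplyr::bind_rows(ev, dplyr::bind_rows(polar))
  ev <- ev[order(ev$time), ]
  tibble::as_tibble(ev)
}

# Longitudes of simple sunrise->sunset day pairs (threshold-free midpoint math).
twilight_pair_lons <- function(ev) {
  ev <- ev[!ev$polar_day %in% TRUE, , drop = FALSE]
  if (nrow(ev) < 2) return(tibble::tibble(date = as.Date(character()), lon = numeric()))
  i <- which(ev$kind[-nrow(ev)] == "sunrise" & ev$kind[-1] == "sunset" &
               diff(as.numeric(ev$time)) < 24 * 3600)
  if (length(i) == 0) return(tibble::tibble(date = as.Date(character()), lon = numeric()))
  mid <- ev$time[i] + (as.numeric(ev$time[i + 1]) - as.numeric(ev$time[i])) / 2
  eq <- solar_ephemeris(mid)$eqtime
  min_day <- (as.numeric(mid) %% 86400) / 60
  tibble::tibble(date = as.Date(mid), lon = wrap_lon((720 - min_day - eq) / 4))
}

#' Validate twilight events
#'
#' Drops ambiguous events (the automated stand-in for manual screening) and
#' then applies an optional per-event override list, which can restore a
#' flagged event (`keep`) or remove an accepted one (`drop`). Overrides are
#' matched to events by timestamp within one minute.
#'
#' @param events output of [detect_twilights()].
#' @param overrides optional tibble with `time` (POSIXct) and `action`
#'   (`"keep"` or `"drop"`).
#' @param quiet suppress the removal-count message.
#' @return Tibble of retained events (columns as in [detect_twilights()]).
#' @export
validate_twilights <- function(events, overrides = NULL, quiet = FALSE) {
  events <- tibble::as_tibble(events)
  keep <- events$quality == "ok"
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      j <- which(abs(as.numeric(events$time) - as.numeric(overrides$time[i])) <= 60)
      if (length(j) > 0) keep[j] <- overrides$action[i] == "keep"
    }
  }
  removed <- sum(!keep)
  if (!quiet && removed > 0) {
    message("validate_twilights: removed ", removed, " of ", nrow(events), " events")
  }
  out <- events[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("all twilight events removed; downstream positions will be empty")
  out
}
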