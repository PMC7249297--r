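#' Simulate an hourly ground-truth track from a scenario
#'
#' Stationary stages are a bounded random walk around the stage anchor:
#' independent east/north hourly steps with standard deviation
#' `step_sd_km / sqrt(24)` (so the daily displacement SD equals
#' `step_sd_km`), reflected at 3 step-SDs from the anchor. Migration stages
#' move along the great circle connecting the neighbouring stage anchors,
#' pausing verbatim at any scripted stopover. Wet/dry state is drawn hourly
#' from the stage's `wet_prob` (stopover hours use the resting level 0.9
#' rather than the flight level).
#'
#' @param scenario a [track_scenario()].
#' @param world a `duck_world`; anchors must fall inside its bounding box.
#' @param seed integer seed; identical seeds give identical tracks.
#' @param step_sd_km daily displacement SD of stationary stages (default 15).
#' @return Tibble with hourly `time` (UTC), `lon`, `lat`, `stage`,
#'   `wet` (logical) and `water_type` (the world's class at the position).
#' @export
simulate_track <- function(scenario, world, seed = 1, step_sd_km = 15) {
  stopifnot(inherits(scenario, "track_scenario"), inherits(world, "duck_world"))
  set.seed(seed)
  st <- scenario$stages
  anchors_ok <- is.na(st$lon) |
    (st$lon >= world$bbox[1] & st$lon <= world$bbox[2] &
       st$lat >= world$bbox[3] & st$lat <= world$bbox[4])
  if (!all(anchors_ok)) stop("scenario error: anchor outside world bounds", call. = FALSE)

  t0 <- as.POSIXct(paste(st$start[1], "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(st$end[nrow(st)], "00:00:00"), tz = "UTC")
  times <- seq(t0, t1 - 3600, by = 3600)
  n <- length(times)
  lon <- lat <- rep(NA_real_, n)
  stage <- character(n)
  wetp <- rep(NA_real_, n)
  day0 <- as.Date(st$start[1])

  hours_of <- function(d_start, d_end) {
    i0 <- as.numeric(as.Date(d_start) - day0) * 24 + 1
    i1 <- as.numeric(as.Date(d_end) - day0) * 24
    seq.int(i0, i1)
  }

  for (i in seq_len(nrow(st))) {
    idx <- hours_of(st$start[i], st$end[i])
    stage[idx] <- st$label[i]
    wetp[idx] <- st$wet_prob[i]
    if (!is.na(st$lon[i])) {
      m <- length(idx)
      sdh <- step_sd_km / sqrt(24)
      lim <- 3 * step_sd_km
      ex <- cumsum(stats::rnorm(m, 0, sdh))
      ny <- cumsum(stats::rnorm(m, 0, sdh))
      reflect <- function(z) {
        z <- ((z + lim) %% (4 * lim))
        ifelse(z > 2 * lim, 4 * lim - z, z) - lim
      }
      ex <- reflect(ex); ny <- reflect(ny)
      lat[idx] <- st$lat[i] + ny / 111.19493
      lon[idx] <- st$lon[i] + ex / (111.19493 * cos(deg2rad(st$lat[i])))
    } else {
      # migration leg: previous anchor -> (stopovers) -> next anchor
      from <- c(st$lon[i - 1], st$lat[i - 1])
      to <- c(st$lon[i + 1], st$lat[i + 1])
      so <- scenario$stopovers
      so <- if (!is.null(so)) so[so$label == st$label[i], , drop = FALSE] else NULL
      waypts <- rbind(from, if (!is.null(so) && nrow(so) > 0) cbind(so$lon, so$lat), to)
      pause_h <- if (!is.null(so) && nrow(so) > 0) so$n_days * 24 else numeric(0)
      m <- length(idx)
      legs <- nrow(waypts) - 1
      dists <- vapply(seq_len(legs), function(k) {
        haversine_km(waypts[k, 1], waypts[k, 2], waypts[k + 1, 1], waypts[k + 1, 2])
      }, numeric(1))
      travel_h <- m - sum(pause_h)
      if (travel_h < legs) stop("scenario error: stopovers exceed migration interval",
                                call. = FALSE)
      leg_h <- pmax(1, round(travel_h * dists / sum(dists)))
      # fix rounding so hours sum exactly
      leg_h[legs] <- travel_h - sum(leg_h[-legs])
      pos <- matrix(NA_real_, 0, 2)
      for (k in seq_len(legs)) {
        p <- geosphere::gcIntermediate(waypts[k, ], waypts[k + 1, ],
                                       n = leg_h[k], addStartEnd = FALSE)
        pos <- rbind(pos, p)
        if (k <= length(pause_h)) {
          pos <- rbind(pos, matrix(rep(waypts[k + 1, ], pause_h[k]),
                                   ncol = 2, byrow = TRUE))
        }
      }
      lon[idx] <- pos[seq_len(m), 1]
      lat[idx] <- pos[seq_len(m), 2]
      # hours in flight are dry; stopover hours rest on water
      moving <- c(TRUE, haversine_km(pos[-1, 1], pos[-1, 2],
                                     pos[-m, 1], pos[-m, 2]) > 0.5)
      wetp[idx][moving] <- 0
      wetp[idx][!moving] <- 0.9
    }
  }
  wet <- stats::runif(n) < wetp
  tibble::tibble(
    time = times, lon = wrap_lon(lon), lat = lat, stage = stage, wet = wet,
    water_type = world$water_class(lon, lat)
  )
}

#' Forward-model the light sensor
#'
#' Per-minute relative light is a monotone saturating (logistic) function of
#' the geometric solar elevation at the bird's position, scaled so that the
#' detection threshold (`threshold` on the 0..`scale_max` logger scale) is
#' crossed exactly when the sun sits at `sun_angle` degrees: this makes
#' `sun_angle` the true calibration angle of the synthetic logger. Shading
#' (dives, plumage, weather) attenuates individual minutes: with probability
#' `p_shade` a minute is multiplied by `exp(-depth)` with lognormal `depth`.
#' The logger stores the maximum over each 5-minute window, rounded to the
#' integer scale.
#'
#' @param truth hourly truth track from [simulate_track()].
#' @param sun_angle true sun-elevation angle at the threshold (default -3.5).
#' @param threshold light threshold the twilight detector will use
#'   (default 2.5, i.e. 2.5% of the scale).
#' @param scale_max top of the logger's relative light scale (default 100).
#' @param width logistic width in degrees of elevation (default 1).
#' @param shading list with `p_shade`, `depth_meanlog`, `depth_sdlog`; set
#'   `p_shade = 0` for noise-free light.
#' @param seed integer seed.
#' @return Tibble `time`, `light` at 5-minute spacing.
#' @export
simulate_light <- function(truth, sun_angle = -3.5, threshold = 2.5,
                           scale_max = 100, width = 1,
                           shading = list(p_shade = 0.3, depth_meanlog = 0,
                                          depth_sdlog = 0.7),
                           seed = 1) {
  set.seed(seed)
  t0 <- truth$time[1]
  n_min <- nrow(truth) * 60
  tmin <- t0 + (seq_len(n_min) - 1) * 60
  hidx <- pmin((seq_len(n_min) - 1) %/% 60 + 1, nrow(truth))
  el <- solar_position(tmin, truth$lon[hidx], truth$lat[hidx])$elevation
  e50 <- sun_angle - width * stats::qlogis(threshold / scale_max)
  light <- scale_max * stats::plogis((el - e50) / width)
  if (shading$p_shade > 0) {
    sh <- stats::runif(n_min) < shading$p_shade
    att <- exp(-stats::rlnorm(sum(sh), shading$depth_meanlog, shading$depth_sdlog))
    light[sh] <- light[sh] * att
  }
  # 5-minute max-pool
  k <- n_min %/% 5
  light <- light[seq_len(5 * k)]
  pooled <- pmax(light[seq(1, 5 * k, 5)], light[seq(2, 5 * k, 5)],
                 light[seq(3, 5 * k, 5)], light[seq(4, 5 * k, 5)],
                 light[seq(5, 5 * k, 5)])
  tibble::tibble(
    time = t0 + (seq_len(k) - 1) * 300,
    light = pmin(pmax(round(pooled), 0L), as.integer(scale_max))
  )
}

#' Forward-model the 4-hour sensor blocks
#'
#' Conductivity, wet/dry and temperature as an archival logger stores them:
#' per 4-hour block the conductivity maximum is drawn around a water-type
#' level (dry ~0, fresh ~3, brackish ~35, sea ~95 on the 0-127 relative
#' scale) and clamped to range; the wet sum is binomial over the block's 480
#' 30-second samples at the hourly wet occupancy; temperature tracks the SST
#' field at the bird's position, perturbed towards air temperature in
#' proportion to the block's dry fraction.
#'
#' @param truth hourly truth track from [simulate_track()].
#' @param world a `duck_world` providing the SST field.
#' @param params list of noise settings: `cond_level` (named numeric),
#'   `cond_sd` (named numeric), `temp_sd`, `air_offset`, `dry_wet_frac`
#'   (occupancy below which a block's conductivity reads dry).
#' @param seed integer seed.
#' @return Tibble `block_start`, `cond_max`, `wet_sum`, `temp_min`,
#'   `temp_mean`, `temp_max`, plus the true `water_type` and `wet_frac`
#'   (simulation bookkeeping used only for validation).
#' @export
simulate_blocks <- function(truth, world,
                            params = list(), seed = 1) {
  set.seed(seed)
  p <- utils::modifyList(list(
    cond_level = c(dry = 1, land_fresh = 3, brackish_sea = 35, open_sea = 95),
    cond_sd = c(dry = 1, land_fresh = 3, brackish_sea = 8, open_sea = 10),
    temp_sd = 0.3, air_offset = 1.5, dry_wet_frac = 0.02
  ), params)
  n_blk <- nrow(truth) %/% 4
  if (n_blk < 1) stop("truth track shorter than one 4-h block", call. = FALSE)
  g <- rep(seq_len(n_blk), each = 4)[seq_len(4 * n_blk)]
  tr <- truth[seq_len(4 * n_blk), ]
  wet_frac <- tapply(as.numeric(tr$wet), g, mean)
  # water type: modal class among wet hours, else modal class overall
  wt <- vapply(split(seq_len(nrow(tr)), g), function(ix) {
    w <- tr$water_type[ix][tr$wet[ix]]
    if (length(w) == 0) w <- tr$water_type[ix]
    names(which.max(table(w)))
  }, character(1))
  eff <- ifelse(wet_frac < p$dry_wet_frac, "dry", wt)
  cond <- stats::rnorm(n_blk, p$cond_level[eff], p$cond_sd[eff])
  cond_max <- as.integer(pmin(pmax(round(cond), 0), 127))
  wet_sum <- stats::rbinom(n_blk, 480, pmin(pmax(wet_frac, 0), 1))
  mid_ix <- seq(2, by = 4, length.out = n_blk)
  sst <- world$sst(tr$lon[mid_ix], tr$lat[mid_ix], as.Date(tr$time[mid_ix]))
  dry_frac <- 1 - wet_frac
  temp_mean <- sst + p$air_offset * dry_frac + stats::rnorm(n_blk, 0, p$temp_sd)
  spread <- 0.3 + 2 * dry_frac
  tibble::tibble(
    block_start = tr$time[seq(1, by = 4, length.out = n_blk)],
    cond_max = cond_max,
    wet_sum = as.integer(wet_sum),
    temp_min = round(temp_mean - spread, 2),
    temp_mean = round(temp_mean, 2),
    temp_max = round(temp_mean + spread, 2),
    water_type = unname(wt),
    wet_frac = unname(as.numeric(wet_frac))
  )
}

#' Simulate a complete logger record for one bird
#'
#' Runs [simulate_track()], [simulate_light()] and [simulate_blocks()] and
#' assembles a [logger_dataset()]. The truth track is attached as the
#' `"truth"` attribute for validation work; nothing downstream reads it.
#'
#' @param scenario a [track_scenario()].
#' @param world a `duck_world`.
#' @param seed integer seed (sub-seeds for track, light and blocks are
#'   derived from it).
#' @param light_args,block_args extra arguments passed to the forward models.
#' @return A `logger_dataset`.
#' @export
simulate_logger <- function(scenario, world, seed = 1,
                            light_args = list(), block_args = list()) {
  truth <- simulate_track(scenario, world, seed = seed)
  light <- do.call(simulate_light,
                   c(list(truth = truth, seed = seed + 1000L), light_args))
  blocks <- do.call(simulate_blocks,
                    c(list(truth = truth, world = world, seed = seed + 2000L),
                      block_args))
  ds <- logger_dataset(
    bird_id = scenario$bird_id,
    deploy_start = truth$time[1],
    deploy_end = truth$time[nrow(truth)] + 3600,
    light = light,
    blocks = blocks[, c("block_start", "cond_max", "wet_sum",
                        "temp_min", "temp_mean", "temp_max")]
  )
  attr(ds, "truth") <- truth
  ds
}
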