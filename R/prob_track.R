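#' Classify sensor blocks into water types
#'
#' A block is `dry` when its wet occupancy (`wet_sum` / 480) falls below the
#' dry threshold, regardless of conductivity; otherwise the conductivity
#' maximum is cut at the class thresholds with half-open intervals:
#' `fresh` below `c_fresh_brackish`, `brackish` in
#' `[c_fresh_brackish, c_brackish_sea)`, `sea` at or above `c_brackish_sea`.
#'
#' @param blocks tibble with `cond_max` and `wet_sum` (a single block row
#'   works too).
#' @param config a [pipeline_config()] carrying the thresholds.
#' @return Character vector in `{dry, fresh, brackish, sea}`.
#' @examples
#' classify_water_type(data.frame(cond_max = c(0, 5, 30, 90), wet_sum = 480))
#' @export
classify_water_type <- function(blocks, config = pipeline_config()) {
  wf <- blocks$wet_sum / 480
  out <- ifelse(wf < config$wet_fraction_dry_threshold, "dry",
                ifelse(blocks$cond_max < config$c_fresh_brackish, "fresh",
                       ifelse(blocks$cond_max < config$c_brackish_sea,
                              "brackish", "sea")))
  as.character(out)
}

#' Particle-based probabilistic track model
#'
#' A forward particle filter over twilight pairs. Per pair, each particle
#' samples twilight-time errors and a sun-elevation angle from the
#' configured band, giving a candidate position by the threshold geometry;
#' where day length carries no latitude information (equinox, polar day) the
#' latitude is drawn from the movement prior around the particle's previous
#' position. Candidates are then rejected on ice, and on land while the
#' logger is wet; weighted by movement feasibility (truncated-lognormal
#' speed likelihood, flight speeds when the block is dry, swim/drift speeds
#' when wet); weighted by agreement between logger temperature and the SST
#' field when wet outside fresh water; and - the conductivity extension -
#' weighted by agreement between the logger's water-type class
#' (fresh/brackish/sea) and the world's class at the candidate, as a hard
#' mask (`conductivity_mode = "hard"`), a soft down-weight (`"soft"`), or
#' not at all (`"off"`, the base model). Fresh blocks disable the marine SST
#' term and, under the extension, permit land/freshwater cells. Systematic
#' resampling keeps `n_particles` particles; if every particle is rejected
#' the pair is retried with inflated twilight error and a hard error is
#' raised after `max_retries` failures. The reported track is the weighted
#' geographic median of each pair's cloud.
#'
#' @param twilights validated twilight events.
#' @param blocks 4-h sensor blocks for the same bird.
#' @param world a `duck_world`.
#' @param start_lon,start_lat tagging location (the filter's initial cloud).
#' @param config a [pipeline_config()].
#' @param conductivity override of `config$conductivity_mode`.
#' @param seed integer seed (defaults to `config$seed`).
#' @param retain_clouds keep per-pair particle clouds (needed for occupancy
#'   diagnostics; ~a few MB per bird-year).
#' @param max_retries retries with doubled error inflation before failing.
#' @return A `duck_track` object: `$track` tibble (per-pair median position,
#'   chosen angle, effective sample size, water class used), `$clouds`
#'   (list of n x 3 matrices lon/lat/angle, if retained), `$config`,
#'   `$seed`.
#' @export
run_prob_track <- function(twilights, blocks, world, start_lon, start_lat,
                           config = pipeline_config(),
                           conductivity = config$conductivity_mode,
                           seed = config$seed, retain_clouds = TRUE,
                           max_retries = 5) {
  stopifnot(inherits(world, "duck_world"))
  set.seed(seed)
  tw <- tibble::as_tibble(twilights)
  pr <- twilight_pairs(tw)
  if (nrow(pr) == 0) stop("no twilight pairs to model", call. = FALSE)
  blocks <- tibble::as_tibble(blocks)
  bclass_all <- classify_water_type(blocks, config)
  bix <- findInterval(as.numeric(pr$mid), as.numeric(blocks$block_start))
  bix[bix < 1] <- 1
  bclass <- bclass_all[bix]
  btemp <- blocks$temp_mean[bix]
  bwet <- blocks$wet_sum[bix] / 480
  # movement regime between consecutive pairs: flight if any block in the
  # between-twilight window was dry, swim/drift otherwise. The water-type
  # class used for weighting is the modal non-dry class of the same window,
  # which keeps a single misread conductivity block from vetoing the pair.
  flight_seg <- logical(nrow(pr))
  for (i in seq_len(nrow(pr))) {
    lo <- if (i == 1) bix[1] else bix[i - 1]
    cl <- bclass_all[lo:bix[i]]
    flight_seg[i] <- any(cl == "dry")
    wetcl <- cl[cl != "dry"]
    bclass[i] <- if (length(wetcl) == 0) "dry" else
      names(which.max(table(wetcl)))
  }

  N <- config$n_particles
  lon_p <- rep(start_lon, N)
  lat_p <- rep(start_lat, N)
  prev_t <- as.numeric(pr$mid[1]) - 12 * 3600
  bb <- world$bbox

  mu_dry <- log(config$speed_dry_mode_ms) + config$speed_sdlog^2
  mu_wet <- log(config$speed_wet_mode_ms) + config$speed_sdlog^2

  n_pairs <- nrow(pr)
  med_lon <- med_lat <- ang_sel <- ess <- rep(NA_real_, n_pairs)
  clouds <- if (retain_clouds) vector("list", n_pairs) else NULL

  for (i in seq_len(n_pairs)) {
    dt_h <- max((as.numeric(pr$mid[i]) - prev_t) / 3600, 1)
    date_i <- as.Date(pr$mid[i])
    wet_blk <- !is.na(bwet[i]) && bwet[i] >= config$wet_fraction_dry_threshold
    # movement-prior latitude spread follows the speed regime's reach
    vmax_kmh <- 3.6 * (if (flight_seg[i]) config$speed_dry_max_ms
                       else config$speed_wet_max_ms)
    prior_sd <- min(config$prior_lat_sd_deg * 3,
                    max(0.25, 0.45 * vmax_kmh * dt_h / 111.19))
    for (try in seq_len(max_retries + 1)) {
      # graded escape: widen the measurement proposal (capped), then relax
      # the speed ceiling, and finally soften the water-type mask
      infl <- min(2^(try - 1), 4)
      spd_infl <- 2^(max(try - 2, 0))
      ang <- stats::runif(N, config$angle_band[1], config$angle_band[2])
      if (pr$type[i] == "polar") {
        lon_c <- pr$lon[i] + stats::rnorm(N, 0, config$polar_lon_sd_deg * infl)
        lat_c <- lat_p + stats::rnorm(N, 0, prior_sd * infl)
      } else {
        e1 <- stats::rnorm(N, 0, config$twilight_err_sd_min * 60 * infl)
        e2 <- stats::rnorm(N, 0, config$twilight_err_sd_min * 60 * infl)
        lon_c <- pr$lon[i] - 15 * ((e1 + e2) / 2) / 3600
        sgn <- if (pr$type[i] == "day") 1 else -1
        dlen <- pr$daylen[i] + sgn * (e2 - e1) / 3600
        lat_c <- latitude_from_day_length(dlen, pr$declination[i], ang,
                                          lat_hint = lat_p)
        # retries treat the pair's latitude as unreliable (movement prior),
        # the standard escape for grazing twilights around the polar day
        if (try >= 2) lat_c[] <- NA_real_
        und <- is.na(lat_c)
        lat_c[und] <- lat_p[und] + stats::rnorm(sum(und), 0, prior_sd * infl)
      }
      lon_c <- wrap_lon(lon_c)
      lat_c <- pmin(pmax(lat_c, -89.9), 89.9)
      w <- rep(1, N)
      inb <- lon_c >= bb[1] & lon_c <= bb[2] & lat_c >= bb[3] & lat_c <= bb[4]
      w[!inb] <- 0
      cls <- rep(NA_character_, N)
      cls[inb] <- world$water_class(lon_c[inb], lat_c[inb])
      ice <- rep(FALSE, N)
      ice[inb] <- world$ice(lon_c[inb], lat_c[inb], date_i)
      w[ice] <- 0
      if (wet_blk) {
        on_land <- !is.na(cls) & cls == "land_fresh"
        if (!(conductivity != "off" && bclass[i] == "fresh")) w[on_land] <- 0
      }
      spd <- haversine_km(lon_p, lat_p, lon_c, lat_c) * 1000 / (dt_h * 3600)
      if (flight_seg[i]) {
        mlik <- stats::dlnorm(pmax(spd, config$speed_dry_mode_ms / 10),
                              mu_dry, config$speed_sdlog)
        mlik[spd > config$speed_dry_max_ms * spd_infl] <- 0
      } else {
        mlik <- stats::dlnorm(pmax(spd, config$speed_wet_mode_ms / 10),
                              mu_wet, config$speed_sdlog)
        mlik[spd > config$speed_wet_max_ms * spd_infl] <- 0
      }
      w <- w * mlik
      if (wet_blk && bclass[i] != "fresh" && is.finite(btemp[i])) {
        sst_c <- rep(NA_real_, N)
        sst_c[inb] <- world$sst(lon_c[inb], lat_c[inb], date_i)
        w <- w * stats::dnorm(btemp[i] - sst_c, 0, config$sst_tolerance)
        w[is.na(w)] <- 0
      }
      if (conductivity != "off" && bclass[i] != "dry") {
        want <- c(sea = "open_sea", brackish = "brackish_sea",
                  fresh = "land_fresh")[bclass[i]]
        mismatch <- is.na(cls) | cls != want
        # the hard mask degrades to the soft weight on the final retries
        soft_now <- conductivity == "soft" || try >= max_retries
        w[mismatch] <- w[mismatch] *
          (if (soft_now) config$conductivity_soft_weight else 0)
      }
      if (any(w > 0) && sum(w) > 0) break
      if (try > max_retries) {
        stop("track error: all particles rejected at pair ", i, " (",
             format(pr$mid[i]), ") after ", max_retries, " retries",
             call. = FALSE)
      }
    }
    wn <- w / sum(w)
    ess[i] <- 1 / sum(wn^2)
    med <- geographic_median(data.frame(lon = lon_c, lat = lat_c),
                             weights = wn, tol = 1e-4, max_iter = 50)
    med_lon[i] <- med["lon"]; med_lat[i] <- med["lat"]
    idx <- systematic_resample(wn, N)
    lon_p <- lon_c[idx]; lat_p <- lat_c[idx]
    ang_sel[i] <- stats::median(ang[idx])
    if (retain_clouds) {
      clouds[[i]] <- cbind(lon = lon_p, lat = lat_p, angle = ang[idx])
    }
    prev_t <- as.numeric(pr$mid[i])
  }
  track <- tibble::tibble(
    pair_id = seq_len(n_pairs), time = pr$mid, date = as.Date(pr$mid),
    lon = med_lon, lat = med_lat, angle = ang_sel, ess = ess,
    type = pr$type, water_class = bclass,
    regime = ifelse(flight_seg, "flight", "wet"), method = "prob_track"
  )
  structure(
    list(track = track, clouds = clouds, config = config, seed = seed,
         conductivity = conductivity, n_particles = N,
         start = c(lon = start_lon, lat = start_lat)),
    class = "duck_track"
  )
}

systematic_resample <- function(w, n) {
  cs <- cumsum(w) / sum(w)
  u <- (stats::runif(1) + seq_len(n) - 1) / n
  pmin(findInterval(u, cs) + 1L, length(w))
}

#' @export
print.duck_track <- function(x, ...) {
  cat("<duck_track>", nrow(x$track), "twilight pairs,", x$n_particles,
      "particles, conductivity:", x$conductivity, "\n",
      " mean effective sample size:", round(mean(x$track$ess), 1), "\n")
  invisible(x)
}

#' Particle occupancy by water class
#'
#' Pools the retained particle clouds of a fitted track over a date interval
#' and reports the fraction of particles in each of the world's water
#' classes - the diagnostic behind the conductivity extension (e.g. the
#' share of "wintering" particles sitting in the wrong basin).
#'
#' @param fit a `duck_track` fitted with `retain_clouds = TRUE`.
#' @param world the `duck_world` the track was fitted against.
#' @param start,end Dates bounding the interval, half-open `[start, end)`.
#' @return Tibble with `class` and `fraction` (sums to 1).
#' @export
basin_occupancy <- function(fit, world, start, end) {
  stopifnot(inherits(fit, "duck_track"))
  if (is.null(fit$clouds)) stop("track was fitted with retain_clouds = FALSE",
                                call. = FALSE)
  ix <- which(fit$track$date >= as.Date(start) & fit$track$date < as.Date(end))
  if (length(ix) == 0) stop("no pairs in the requested interval", call. = FALSE)
  pts <- do.call(rbind, fit$clouds[ix])
  cls <- world$water_class(pts[, "lon"], pts[, "lat"])
  tb <- table(factor(cls, levels = c("land_fresh", "brackish_sea", "open_sea")))
  tibble::tibble(class = names(tb), fraction = as.numeric(tb) / sum(tb))
}
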