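#' Build a scripted annual-cycle scenario
#'
#' A scenario is the ground-truth itinerary a synthetic bird follows: an
#' ordered, contiguous sequence of the six staging periods, each with an
#' anchor location and a wet/dry behaviour level, plus optional scripted
#' stopovers inside migration stages. Migration stages connect the anchors of
#' their neighbouring stages; their own `lon`/`lat` may be `NA`. A migration
#' row may give `speed_kmh` instead of an end date, in which case the end is
#' computed from the great-circle route length.
#'
#' @param stages tibble with columns `label` (one of `breeding`,
#'   `post_moult`, `autumn_migration`, `wintering`, `spring_migration`,
#'   `pre_breeding`; `breeding` may open and close the cycle), `start`, `end`
#'   (Dates, half-open `[start, end)`), `lon`, `lat` (anchor, degrees),
#'   optionally `wet_prob` (probability an hour is spent on water) and
#'   `speed_kmh`.
#' @param stopovers optional tibble with columns `label` (the parent
#'   migration stage), `start` (Date), `n_days`, `lon`, `lat`.
#' @param bird_id identifier carried through the pipeline.
#' @return An object of class `track_scenario`.
#' @export
track_scenario <- function(stages, stopovers = NULL, bird_id = "bird") {
  stages <- tibble::as_tibble(stages)
  labs <- c("breeding", "post_moult", "autumn_migration", "wintering",
            "spring_migration", "pre_breeding")
  if (!all(stages$label %in% labs)) {
    stop("scenario error: unknown stage label", call. = FALSE)
  }
  stages$start <- as.Date(stages$start)
  if (!"wet_prob" %in% names(stages)) stages$wet_prob <- NA_real_
  if (!"speed_kmh" %in% names(stages)) stages$speed_kmh <- NA_real_
  defaults <- c(breeding = 0.55, post_moult = 0.92, autumn_migration = 0.15,
                wintering = 0.96, spring_migration = 0.15, pre_breeding = 0.92)
  stages$wet_prob <- ifelse(is.na(stages$wet_prob),
                            unname(defaults[stages$label]), stages$wet_prob)
  stages$end <- as.Date(stages$end)
  # derive missing migration ends from route length and speed
  for (i in seq_len(nrow(stages))) {
    if (is.na(stages$end[i])) {
      if (is.na(stages$speed_kmh[i]) || i == 1 || i == nrow(stages)) {
        stop("scenario error: stage without end date needs speed_kmh and neighbours",
             call. = FALSE)
      }
      d <- haversine_km(stages$lon[i - 1], stages$lat[i - 1],
                        stages$lon[i + 1], stages$lat[i + 1])
      hrs <- ceiling(d / stages$speed_kmh[i])
      stages$end[i] <- stages$start[i] + ceiling(hrs / 24)
      if (i < nrow(stages)) stages$start[i + 1] <- stages$end[i]
    }
  }
  if (any(diff(as.numeric(stages$start)) <= 0) ||
      any(stages$end <= stages$start)) {
    stop("scenario error: stages must be ordered with positive duration",
         call. = FALSE)
  }
  if (nrow(stages) > 1 &&
      any(stages$end[-nrow(stages)] != stages$start[-1])) {
    stop("scenario error: stages must be contiguous", call. = FALSE)
  }
  if (!is.null(stopovers)) {
    stopovers <- tibble::as_tibble(stopovers)
    stopovers$start <- as.Date(stopovers$start)
  }
  structure(list(stages = stages, stopovers = stopovers, bird_id = bird_id),
            class = "track_scenario")
}

#' Default 19-bird synthetic cohort
#'
#' Scripted itineraries emulating the study conditions of a female
#' long-tailed duck cohort tagged on an Arctic tundra island: breeding at
#' freshwater lakes near 69.1N 48.8E, a marine post-moult stage starting
#' 12 Sep +- 11 days and lasting 33 +- 10 days, a rapid autumn migration
#' (a few days; four birds pause at White Sea longitudes 35, 39, 38 and 38 E
#' for 4, 7, 6 and 3 days), wintering for 212 +- 3 days in the brackish
#' Baltic-like basin (18 birds) or the marine White-Sea-like embayment (1
#' bird), a rapid spring migration and a coastal marine pre-breeding stage of
#' 23 +- 7 days before the next breeding season. Deployments last 364 +- 11
#' days from about 20 June.
#'
#' @param n_birds number of birds (default 19; the last bird is the White
#'   Sea winterer when `n_birds >= 2`).
#' @param seed integer seed for the itinerary draws.
#' @param world a `duck_world` used to sanity-check anchors.
#' @return A list with `scenarios` (list of `track_scenario`) and `design`
#'   (tibble of scripted boundary dates, anchors and per-bird metadata).
#' @export
default_cohort <- function(n_birds = 19, seed = 1, world = default_world()) {
  set.seed(seed)
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  rdate <- function(base, sd, lo, hi) {
    as.Date(base) + round(clip(stats::rnorm(n_birds, 0, sd),
                               as.numeric(as.Date(lo) - as.Date(base)),
                               as.numeric(as.Date(hi) - as.Date(base))))
  }
  deploy_start <- rdate("2017-06-20", 4, "2017-06-12", "2017-06-28")
  pm_start <- rdate("2017-09-12", 11, "2017-08-29", "2017-10-07")
  pm_dur <- round(clip(stats::rnorm(n_birds, 33, 10), 19, 50))
  stop_birds <- if (n_birds >= 5) 1:4 else integer(0)
  stop_lon <- c(35, 39, 38, 38); stop_days <- c(4, 7, 6, 3)
  travel <- round(clip(stats::rnorm(n_birds, 2, 1), 1, 4))
  am_dur <- travel
  am_dur[stop_birds] <- travel[stop_birds] + stop_days[seq_along(stop_birds)]
  win_dur <- round(clip(stats::rnorm(n_birds, 212, 3), 197, 229))
  sm_dur <- round(clip(stats::rnorm(n_birds, 2, 1), 1, 6))
  pb_dur <- round(clip(stats::rnorm(n_birds, 23, 7), 13, 34))

  # anchor clips keep the 3-step-SD random walk (45 km, ~1.1 deg lon at
  # these latitudes) inside the stage's water-type region
  br_lon <- clip(48.848 + stats::rnorm(n_birds, 0, 0.5), 47.3, 50.7)
  br_lat <- clip(69.138 + stats::rnorm(n_birds, 0, 0.2), 68.8, 69.5)
  pmo_lon <- clip(stats::rnorm(n_birds, 49, 2.5), 44, 53.5)
  pmo_lat <- clip(stats::rnorm(n_birds, 70.55, 0.15), 70.45, 70.9)
  win_lon <- clip(stats::rnorm(n_birds, 21, 3), 16, 28.5)
  win_lat <- clip(stats::rnorm(n_birds, 58, 1.4), 55, 60.7)
  if (n_birds >= 2) { win_lon[n_birds] <- 38; win_lat[n_birds] <- 65 }
  pb_lon <- clip(stats::rnorm(n_birds, 44, 1), 42.2, 44.8)
  pb_lat <- clip(stats::rnorm(n_birds, 67.6, 0.1), 67.45, 67.8)
  if (n_birds >= 2) { pb_lon[n_birds] <- 50; pb_lat[n_birds] <- 67.6 }

  am_start <- pm_start + pm_dur
  win_start <- am_start + am_dur
  sm_start <- win_start + win_dur
  pb_start <- sm_start + sm_dur
  br2_start <- pb_start + pb_dur
  deploy_len <- round(clip(stats::rnorm(n_birds, 364, 11), 356, 403))
  deploy_end <- pmax(deploy_start + deploy_len, br2_start + 5)

  ids <- sprintf("SB%03d", seq_len(n_birds))
  scenarios <- vector("list", n_birds)
  for (b in seq_len(n_birds)) {
    stages <- tibble::tibble(
      label = c("breeding", "post_moult", "autumn_migration", "wintering",
                "spring_migration", "pre_breeding", "breeding"),
      start = c(deploy_start[b], pm_start[b], am_start[b], win_start[b],
                sm_start[b], pb_start[b], br2_start[b]),
      end = c(pm_start[b], am_start[b], win_start[b], sm_start[b],
              pb_start[b], br2_start[b], deploy_end[b]),
      lon = c(br_lon[b], pmo_lon[b], NA, win_lon[b], NA, pb_lon[b], br_lon[b]),
      lat = c(br_lat[b], pmo_lat[b], NA, win_lat[b], NA, pb_lat[b], br_lat[b])
    )
    so <- NULL
    k <- match(b, stop_birds)
    if (!is.na(k)) {
      so <- tibble::tibble(
        label = "autumn_migration",
        start = am_start[b] + 1,
        n_days = stop_days[k],
        lon = stop_lon[k], lat = 65.5
      )
    }
    scenarios[[b]] <- track_scenario(stages, stopovers = so, bird_id = ids[b])
  }
  design <- tibble::tibble(
    bird_id = ids, deploy_start = deploy_start, deploy_end = deploy_end,
    breeding_lon = br_lon, breeding_lat = br_lat,
    post_moult_start = pm_start, post_moult_lon = pmo_lon,
    post_moult_lat = pmo_lat,
    autumn_migration_start = am_start,
    wintering_start = win_start, wintering_lon = win_lon,
    wintering_lat = win_lat,
    spring_migration_start = sm_start,
    pre_breeding_start = pb_start, pre_breeding_lon = pb_lon,
    pre_breeding_lat = pb_lat,
    breeding2_start = br2_start,
    winter_basin = ifelse(seq_len(n_birds) == n_birds & n_birds >= 2,
                          "white_sea", "baltic"),
    autumn_stopover_days = ifelse(seq_len(n_birds) %in% stop_birds,
                                  stop_days[match(seq_len(n_birds), stop_birds)], 0)
  )
  list(scenarios = scenarios, design = design)
}
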