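#' Daily longitude and water-type summaries
#'
#' Collapses twilight-pair positions and 4-h sensor blocks to the daily
#' series the stage rules operate on. Daily longitude is the median of the
#' (at most two) pair longitudes of the day; days with no valid longitude
#' inherit the previous day's value and are flagged. Daily water-type
#' summaries: the modal class among wet blocks (`NA` on all-dry days), and
#' whether every block of the day was fresh or dry.
#'
#' @param positions tibble from [positions_from_twilights()] or a
#'   `duck_track`'s `$track`.
#' @param blocks sensor blocks with `block_start`, `cond_max`, `wet_sum`.
#' @param config a [pipeline_config()].
#' @return Tibble: `date`, `lon`, `lon_inherited`, `polar`, `wet_class`,
#'   `all_fresh_dry`, `n_blocks`.
#' @export
daily_summaries <- function(positions, blocks, config = pipeline_config()) {
  pos <- tibble::as_tibble(positions)
  blocks <- tibble::as_tibble(blocks)
  blocks$class <- classify_water_type(blocks, config)
  blocks$date <- as.Date(blocks$block_start)
  bl <- dplyr::summarise(
    dplyr::group_by(blocks, date),
    wet_class = {
      w <- class[class != "dry"]
      if (length(w) == 0) NA_character_ else names(which.max(table(w)))
    },
    all_fresh_dry = all(class %in% c("fresh", "dry")),
    n_blocks = dplyr::n(),
    .groups = "drop"
  )
  po <- dplyr::summarise(
    dplyr::group_by(pos, date = as.Date(time)),
    lon_obs = stats::median(lon, na.rm = TRUE),
    polar = any(type == "polar"),
    .groups = "drop"
  )
  days <- tibble::tibble(date = seq(min(bl$date, po$date), max(bl$date, po$date),
                                    by = "day"))
  out <- dplyr::left_join(days, po, by = "date")
  out <- dplyr::left_join(out, bl, by = "date")
  out$polar[is.na(out$polar)] <- FALSE
  out$lon_inherited <- is.na(out$lon_obs)
  lon <- out$lon_obs
  for (i in seq_along(lon)) if (is.na(lon[i]) && i > 1) lon[i] <- lon[i - 1]
  if (anyNA(lon) && any(!is.na(lon))) {
    lon[is.na(lon)] <- lon[which(!is.na(lon))[1]]
  }
  out$lon <- lon
  out$n_blocks[is.na(out$n_blocks)] <- 0L
  out[, c("date", "lon", "lon_inherited", "polar", "wet_class",
          "all_fresh_dry", "n_blocks")]
}

#' Segment one bird-year into the six staging periods
#'
#' A deterministic rule set over the daily summaries, operationalising the
#' longitude/conductivity stage definitions. The deployment opens in the
#' breeding stage. Post-moult begins on the first day the bird leaves fresh
#' water (any brackish/sea block) or the running 7-day longitude range
#' exceeds `lon_stable_deg`. A migration begins on the first of two
#' consecutive days displaced more than `migration_exit_deg` from the
#' running median longitude of the current stationary stage (a band-exit
#' rule: immune to day-to-day jitter that stays inside the stage's
#' longitudinal range, e.g. 3-degree jitter within an 8-degree wintering
#' range never triggers a false migration). Autumn migration ends and
#' wintering begins on the first day from which the longitudes of the next
#' `stationary_min_days` days stay within `wintering_range_deg` (10 degrees)
#' with an unchanged modal water-type class - stopover pauses, being
#' shorter, never satisfy this. Spring migration ends symmetrically with
#' the pre-breeding constancy window widened to `prebreeding_range_deg`
#' (15 degrees, reflecting polar-day longitude inaccuracy). Breeding
#' resumes on the first of three consecutive fresh-or-dry-only days.
#' Intervals are half-open `[start, end)` at day resolution, contiguous,
#' and cover the deployment; absent transitions simply leave later stages
#' out (a bird that never leaves fresh water is a single breeding interval).
#'
#' @param daily tibble from [daily_summaries()].
#' @param config a [pipeline_config()].
#' @param overrides optional tibble `stage`, `start` pinning stage onsets
#'   per bird (applied after the rules).
#' @param bird_id identifier carried into the result.
#' @return A `stage_segmentation`: list with `intervals` (tibble `label`,
#'   `start`, `end`, `n_days`, `mean_lon`, `sd_lon`), `stopovers` (filled by
#'   [detect_stopovers()]), `daily`, `bird_id`.
#' @export
segment_annual_cycle <- function(daily, config = pipeline_config(),
                                 overrides = NULL, bird_id = "bird") {
  d <- tibble::as_tibble(daily)
  if (mean(is.na(d$wet_class) & !d$all_fresh_dry %in% TRUE & d$n_blocks == 0) > 0.2) {
    stop("segmentation error: water types missing on more than 20% of days",
         call. = FALSE)
  }
  n <- nrow(d)
  lon <- d$lon
  marine_day <- !is.na(d$wet_class) & d$wet_class %in% c("brackish", "sea")
  # modal-class freshness is robust to a single misread conductivity block
  freshdry_day <- is.na(d$wet_class) | d$wet_class == "fresh"
  # polar-day longitudes are much noisier; widen the tolerance accordingly
  recent_polar <- vapply(seq_len(n), function(i)
    any(d$polar[max(1, i - 2):i]), logical(1))

  run_range <- function(i, k) {
    ix <- seq(max(1, i - k + 1), i)
    diff(range(lon[ix], na.rm = TRUE))
  }
  fwd_range <- function(i, k) {
    ix <- seq(i, min(n, i + k - 1))
    diff(range(lon[ix], na.rm = TRUE))
  }
  fwd_class_const <- function(i, k) {
    ix <- seq(i, min(n, i + k - 1))
    cl <- d$wet_class[ix]
    length(unique(cl[!is.na(cl)])) <= 1
  }
  band_exit <- function(from, ref_fun, band) {
    # first of migration_min_run + 1 consecutive days outside the band
    # around the running reference longitude
    need <- config$migration_min_run + 1
    i <- from
    while (i < n) {
      ref <- ref_fun(i)
      days <- lon[i:min(i + need - 1, n)]
      if (length(days) == need && all(abs(days - ref) > band)) return(i)
      i <- i + 1
    }
    NA_integer_
  }

  b <- rep(NA_integer_, 6) # onsets of stages II..VI and breeding II
  # II: post-moult - first departure from fresh water, flagged by marine
  # blocks or by a sustained longitude shift away from the breeding site
  ref_br <- stats::median(lon[seq_len(min(14, n))], na.rm = TRUE)
  med3 <- vapply(seq_len(n), function(i)
    stats::median(lon[max(1, i - 2):i], na.rm = TRUE), numeric(1))
  lon_tol <- ifelse(recent_polar, config$prebreeding_range_deg,
                    config$migration_exit_deg)
  cand <- which(marine_day | abs(med3 - ref_br) > lon_tol)
  cand <- cand[cand > 1]
  b[1] <- if (length(cand) > 0) cand[1] else NA_integer_

  if (!is.na(b[1])) {
    # III: autumn migration - band exit from the post-moult longitude
    ref_pm <- function(i) stats::median(lon[b[1]:max(b[1], i - 1)], na.rm = TRUE)
    b[2] <- band_exit(b[1] + 1, ref_pm, config$migration_exit_deg)
  }
  if (!is.na(b[2])) {
    # IV: wintering - displacement has settled and a long stable window opens
    i <- b[2] + 1
    while (i <= n) {
      if (abs(lon[i] - lon[i - 1]) < config$migration_rate_deg_per_day &&
          fwd_range(i, config$stationary_min_days) < config$wintering_range_deg &&
          fwd_class_const(i, config$stationary_min_days)) break
      i <- i + 1
    }
    b[3] <- if (i <= n) i else NA_integer_
  }
  if (!is.na(b[3])) {
    # V: spring migration - band exit from the running wintering median
    ref_win <- function(i) stats::median(lon[max(b[3], i - 14):(i - 1)], na.rm = TRUE)
    b[4] <- band_exit(b[3] + config$stationary_min_days, ref_win,
                      config$migration_exit_deg)
  }
  if (!is.na(b[4])) {
    # VI: pre-breeding - displacement drops and a 15-degree window holds
    i <- b[4] + 1
    while (i <= n) {
      disp <- abs(lon[i] - lon[i - 1])
      if (disp < config$migration_rate_deg_per_day &&
          fwd_range(i, 7) < config$prebreeding_range_deg) break
      i <- i + 1
    }
    b[5] <- if (i <= n) i else NA_integer_
  }
  if (!is.na(b[5])) {
    # I again: breeding - three consecutive fresh-or-dry-only days
    i <- b[5] + 1
    while (i + 2 <= n) {
      if (all(freshdry_day[i:(i + 2)])) break
      i <- i + 1
    }
    b[6] <- if (i + 2 <= n) i else NA_integer_
  }

  labels <- c("breeding", "post_moult", "autumn_migration", "wintering",
              "spring_migration", "pre_breeding", "breeding")
  onsets <- c(1, b)
  if (!is.null(overrides)) {
    for (j in seq_len(nrow(overrides))) {
      k <- which(labels == overrides$stage[j])
      k <- k[k > 1][1]
      if (!is.na(k)) onsets[k] <- match(as.Date(overrides$start[j]), d$date)
    }
  }
  keep <- !is.na(onsets)
  ends <- c(onsets[keep][-1], n + 1)
  if (any(diff(onsets[keep]) <= 0)) {
    stop("segmentation error: cycle-order violation at transition to ",
         labels[keep][which(diff(onsets[keep]) <= 0)[1] + 1], call. = FALSE)
  }
  iv <- tibble::tibble(
    label = labels[keep],
    start = d$date[onsets[keep]],
    end = c(d$date[onsets[keep][-1]], d$date[n] + 1),
    n_days = as.numeric(ends - onsets[keep])
  )
  iv$mean_lon <- vapply(seq_len(nrow(iv)), function(j) {
    mean(lon[d$date >= iv$start[j] & d$date < iv$end[j]], na.rm = TRUE)
  }, numeric(1))
  iv$sd_lon <- vapply(seq_len(nrow(iv)), function(j) {
    stats::sd(lon[d$date >= iv$start[j] & d$date < iv$end[j]])
  }, numeric(1))
  structure(list(intervals = iv, stopovers = NULL, daily = d, bird_id = bird_id),
            class = "stage_segmentation")
}

#' @export
print.stage_segmentation <- function(x, ...) {
  cat("<stage_segmentation> bird", x$bird_id, "\n")
  print(x$intervals)
  invisible(x)
}

#' Detect stopovers inside migration stages
#'
#' A stopover is a maximal run of at least two days inside a migration
#' interval whose longitudes stay within `lon_stable_deg` of each other.
#' Each stopover reports its mean longitude and whether that longitude falls
#' in the White Sea band (33.9-41.6 E).
#'
#' @param seg a `stage_segmentation`.
#' @param config a [pipeline_config()].
#' @return The segmentation with its `stopovers` tibble filled
#'   (`label`, `start`, `end`, `n_days`, `mean_lon`, `white_sea`).
#' @export
detect_stopovers <- function(seg, config = pipeline_config()) {
  stopifnot(inherits(seg, "stage_segmentation"))
  d <- seg$daily
  res <- list()
  for (j in which(seg$intervals$label %in% c("autumn_migration", "spring_migration"))) {
    iv <- seg$intervals[j, ]
    ix <- which(d$date >= iv$start & d$date < iv$end)
    if (length(ix) < 2) next
    lon <- d$lon[ix]
    i <- 1
    while (i <= length(ix)) {
      k <- i
      while (k < length(ix) &&
             diff(range(lon[i:(k + 1)])) < config$lon_stable_deg) k <- k + 1
      if (k - i + 1 >= 2) {
        ml <- mean(lon[i:k])
        res[[length(res) + 1]] <- tibble::tibble(
          label = iv$label, start = d$date[ix[i]], end = d$date[ix[k]] + 1,
          n_days = k - i + 1, mean_lon = ml,
          white_sea = ml >= 33.9 & ml <= 41.6
        )
      }
      i <- k + 1
    }
  }
  seg$stopovers <- if (length(res) > 0) dplyr::bind_rows(res) else
    tibble::tibble(label = character(), start = as.Date(character()),
                   end = as.Date(character()), n_days = numeric(),
                   mean_lon = numeric(), white_sea = logical())
  seg
}

#' Great-circle track length inside an interval
#'
#' Sum of haversine distances between consecutive median positions whose
#' times fall in the half-open interval. By default positions are first
#' collapsed to one geographic median per day and steps below `min_step_km`
#' are treated as position noise around a stationary bird (stopover jitter)
#' and contribute zero - without this floor, twice-daily position scatter
#' at a multi-day stopover adds hundreds of spurious kilometres. Set
#' `daily = FALSE, min_step_km = 0` for the raw per-pair path length. With
#' fewer than two positions the distance is undefined and reported as `NA`,
#' never zero.
#'
#' @param track a `duck_track` or a tibble with `time`/`date`, `lon`, `lat`.
#' @param start,end Dates bounding the interval.
#' @param daily collapse to daily median positions first (default TRUE).
#' @param min_step_km steps shorter than this count as zero (default 75,
#'   well above geolocator position scatter and far below any real
#'   migration-day displacement for this species).
#' @param pad_days widen the interval by this many days on each side
#'   (default 1), so that the step from the last pre-migration day to the
#'   first travel day - and the arrival step - are counted; at day
#'   resolution a strictly interior path misses up to a day of travel at
#'   each end.
#' @param stationary_only when the track carries a `regime` column (a
#'   `duck_track` does), use only water-contact positions as waypoints
#'   (default TRUE). Threshold positions taken while a bird is in flight
#'   are systematically distorted - within-pair longitude change smears the
#'   apparent day length - so the reliable route is the one through resting
#'   positions (departure area, stopovers, arrival area).
#' @return Distance in km, or `NA_real_`.
#' @examples
#' migration_distance(data.frame(date = Sys.Date() + 0:1,
#'                               lon = c(0, 1), lat = c(0, 0)),
#'                    Sys.Date(), Sys.Date() + 2, min_step_km = 0, pad_days = 0)
#' @export
migration_distance <- function(track, start, end, daily = TRUE,
                               min_step_km = 75, pad_days = 1,
                               stationary_only = TRUE) {
  tr <- if (inherits(track, "duck_track")) track$track else tibble::as_tibble(track)
  if (!"date" %in% names(tr)) tr$date <- as.Date(tr$time)
  use_regime <- stationary_only && "regime" %in% names(tr)
  # resting positions flanking a short flight can sit 2-3 days outside the
  # detected interval; search a little wider when regime-filtering
  pad_eff <- if (use_regime) pad_days + 2 else pad_days
  tr <- tr[tr$date >= as.Date(start) - pad_eff &
             tr$date < as.Date(end) + pad_eff &
             !is.na(tr$lon) & !is.na(tr$lat), ]
  if (use_regime && sum(tr$regime == "wet") >= 2) {
    tr <- tr[tr$regime == "wet", ]
  }
  if (nrow(tr) < 2) return(NA_real_)
  if (daily) {
    tr <- dplyr::summarise(dplyr::group_by(tr, date),
                           lon = stats::median(lon), lat = stats::median(lat),
                           .groups = "drop")
    if (nrow(tr) < 2) return(NA_real_)
  }
  steps <- haversine_km(tr$lon[-nrow(tr)], tr$lat[-nrow(tr)],
                        tr$lon[-1], tr$lat[-1])
  sum(steps[steps >= min_step_km])
}

#' Cohort phenology table
#'
#' Per-stage summaries across birds: mean +- SD (sample SD, n-1) and range
#' of start date, end date and duration; mean longitude; and for migration
#' stages the great-circle distance along the probabilistic median track.
#' The breeding-stage duration is estimated from the surrounding boundaries
#' (second-year breeding onset to the post-moult onset, folded to one year),
#' since a deployment never spans a full breeding stage. For `n = 1` the SD
#' is `NA` and the range collapses to the single value.
#'
#' @param segmentations list of `stage_segmentation` objects.
#' @param tracks optional named list of `duck_track` objects (names = bird
#'   ids) used for migration distances.
#' @return Tibble: `stage`, `statistic`, `mean` (formatted; dates as
#'   ISO strings), `value` (numeric mean for non-date statistics), `sd`
#'   (days/degrees/km), `min`, `max`, `n`.
#' @export
phenology_summary <- function(segmentations, tracks = NULL) {
  if (inherits(segmentations, "stage_segmentation")) {
    segmentations <- list(segmentations)
  }
  rows <- purrr::map_dfr(segmentations, function(s) {
    iv <- s$intervals
    iv$bird_id <- s$bird_id
    iv
  })
  # second breeding interval per bird gets its own label for reporting
  rows <- dplyr::group_by(rows, bird_id, label)
  rows <- dplyr::mutate(rows, occurrence = dplyr::row_number())
  rows <- dplyr::ungroup(rows)
  rows$stage <- ifelse(rows$label == "breeding" & rows$occurrence == 2,
                       "breeding_2", rows$label)

  summar <- function(x) {
    is_date <- inherits(x, "Date")
    x <- x[!is.na(x)]
    n <- length(x)
    fmt <- function(v) {
      if (n == 0) return(NA_character_)
      if (is_date) format(v, "%Y-%m-%d") else as.character(round(v, 4))
    }
    tibble::tibble(
      mean = fmt(if (n > 0) mean(x) else NA),
      value = if (n > 0 && !is_date) mean(as.numeric(x)) else NA_real_,
      sd = if (n > 1) stats::sd(as.numeric(x)) else NA_real_,
      min = fmt(if (n > 0) min(x) else NA),
      max = fmt(if (n > 0) max(x) else NA),
      n = n
    )
  }
  stage_order <- c("breeding", "post_moult", "autumn_migration", "wintering",
                   "spring_migration", "pre_breeding", "breeding_2")
  out <- list()
  for (st in intersect(stage_order, unique(rows$stage))) {
    r <- rows[rows$stage == st, ]
    for (stat in c("start", "end", "duration_days", "mean_lon")) {
      v <- switch(stat, start = r$start, end = r$end,
                  duration_days = r$n_days, mean_lon = r$mean_lon)
      # opening/closing breeding fragments have censored boundaries
      if (st == "breeding" && stat %in% c("start", "duration_days")) next
      if (st == "breeding_2" && stat %in% c("end", "duration_days")) next
      s <- summar(v)
      out[[length(out) + 1]] <- dplyr::bind_cols(
        tibble::tibble(stage = st, statistic = stat), s)
    }
  }
  # estimated breeding duration: second-year onset to post-moult onset (folded)
  est <- purrr::map_dbl(segmentations, function(s) {
    iv <- s$intervals
    br2 <- iv$start[iv$label == "breeding"][2]
    pm <- iv$start[iv$label == "post_moult"][1]
    if (is.na(br2) || length(pm) == 0 || is.na(pm)) return(NA_real_)
    as.numeric(pm - (br2 - 365))
  })
  s <- summar(est)
  out[[length(out) + 1]] <- dplyr::bind_cols(
    tibble::tibble(stage = "breeding", statistic = "duration_days_estimated"), s)

  if (!is.null(tracks)) {
    for (st in c("autumn_migration", "spring_migration")) {
      dists <- purrr::map_dbl(segmentations, function(s) {
        tr <- tracks[[s$bird_id]]
        iv <- s$intervals[s$intervals$label == st, ]
        if (is.null(tr) || nrow(iv) == 0) return(NA_real_)
        migration_distance(tr, iv$start[1], iv$end[1])
      })
      s <- summar(dists)
      out[[length(out) + 1]] <- dplyr::bind_cols(
        tibble::tibble(stage = st, statistic = "distance_km"), s)
    }
  }
  dplyr::bind_rows(out)
}
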