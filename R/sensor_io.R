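#' Assemble and validate a logger dataset
#'
#' The in-memory representation of one bird's raw archival record: a
#' relative-light series (maximum per 5 min) and 4-hourly sensor blocks
#' (conductivity maximum on the 0-127 relative scale, wet/dry sum on the
#' 0-480 scale at 30-s sampling, temperature min/mean/max in degC), plus
#' deployment metadata. All timestamps are UTC. Invariants are checked on
#' construction: strictly increasing light timestamps on a 300-s raster
#' (gaps allowed and counted), block spacing on a 4-h raster, sensor values
#' in range, `temp_min <= temp_mean <= temp_max`.
#'
#' @param bird_id identifier string.
#' @param deploy_start,deploy_end POSIXct UTC deployment bounds, half-open.
#' @param light tibble with `time` (POSIXct UTC) and `light` (integer >= 0).
#' @param blocks tibble with `block_start`, `cond_max`, `wet_sum`,
#'   `temp_min`, `temp_mean`, `temp_max`.
#' @param clock_drift_corrected flag recording the assumption that the
#'   logger clock was drift-corrected upstream (default TRUE).
#' @return An object of class `logger_dataset`.
#' @export
logger_dataset <- function(bird_id, deploy_start, deploy_end, light, blocks,
                           clock_drift_corrected = TRUE) {
  light <- tibble::as_tibble(light)
  blocks <- tibble::as_tibble(blocks)
  if (!all(c("time", "light") %in% names(light))) {
    stop("format error: light needs columns time, light", call. = FALSE)
  }
  bcols <- c("block_start", "cond_max", "wet_sum", "temp_min", "temp_mean", "temp_max")
  if (!all(bcols %in% names(blocks))) {
    stop("format error: blocks need columns ", paste(bcols, collapse = ", "),
         call. = FALSE)
  }
  dt <- diff(as.numeric(light$time))
  if (nrow(light) > 1) {
    bad <- which(dt <= 0)
    if (length(bad) > 0) {
      stop("data error: non-monotonic light timestamps at row ", bad[1] + 1,
           call. = FALSE)
    }
    offgrid <- which(dt %% 300 != 0)
    if (length(offgrid) > 0) {
      stop("data error: light timestamps off the 300-s raster at row ",
           offgrid[1] + 1, call. = FALSE)
    }
  }
  if (any(light$light < 0)) {
    stop("data error: negative light at row ", which(light$light < 0)[1],
         call. = FALSE)
  }
  bad <- which(blocks$cond_max < 0 | blocks$cond_max > 127)
  if (length(bad) > 0) {
    stop("data error: cond_max outside the 0-127 relative scale at block ",
         bad[1], call. = FALSE)
  }
  bad <- which(blocks$wet_sum < 0 | blocks$wet_sum > 480)
  if (length(bad) > 0) {
    stop("data error: wet_sum outside the 0-480 scale at block ", bad[1],
         call. = FALSE)
  }
  bad <- which(!(blocks$temp_min <= blocks$temp_mean &
                   blocks$temp_mean <= blocks$temp_max))
  if (length(bad) > 0) {
    stop("data error: temperature ordering violated at block ", bad[1],
         call. = FALSE)
  }
  if (nrow(blocks) > 1) {
    bdt <- diff(as.numeric(blocks$block_start))
    bad <- which(bdt <= 0 | bdt %% 14400 != 0)
    if (length(bad) > 0) {
      stop("data error: block spacing off the 4-h raster at block ", bad[1] + 1,
           call. = FALSE)
    }
  }
  structure(
    list(
      bird_id = as.character(bird_id),
      deploy_start = lubridate::with_tz(deploy_start, "UTC"),
      deploy_end = lubridate::with_tz(deploy_end, "UTC"),
      light = light, blocks = blocks,
      n_light_gaps = if (nrow(light) > 1) sum(dt > 300) else 0L,
      clock_drift_corrected = isTRUE(clock_drift_corrected)
    ),
    class = "logger_dataset"
  )
}

#' @export
print.logger_dataset <- function(x, ...) {
  cat("<logger_dataset> bird", x$bird_id, "\n",
      " deployment:", format(x$deploy_start), "to", format(x$deploy_end), "UTC\n",
      " light samples:", nrow(x$light), "(", x$n_light_gaps, "gaps )\n",
      " sensor blocks:", nrow(x$blocks), "\n")
  invisible(x)
}

#' Write a logger dataset to the native CSV dialect
#'
#' Two plain CSV files, `<prefix>_light.csv` and `<prefix>_blocks.csv`, each
#' opened by a one-line JSON metadata header (prefixed `#`) followed by the
#' column header. Human-readable and round-trip exact at 1-s timestamp
#' resolution.
#'
#' @param ds a `logger_dataset`.
#' @param prefix path prefix for the two files.
#' @return The two file paths, invisibly.
#' @export
write_logger_export <- function(ds, prefix) {
  stopifnot(inherits(ds, "logger_dataset"))
  meta <- jsonlite::toJSON(list(
    bird_id = ds$bird_id,
    deploy_start = format(ds$deploy_start, "%Y-%m-%dT%H:%M:%SZ"),
    deploy_end = format(ds$deploy_end, "%Y-%m-%dT%H:%M:%SZ"),
    clock_drift_corrected = ds$clock_drift_corrected
  ), auto_unbox = TRUE)
  wr <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", meta), con)
    df[[1]] <- format(df[[1]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    utils::write.csv(df, con, row.names = FALSE)
  }
  paths <- paste0(prefix, c("_light.csv", "_blocks.csv"))
  wr(ds$light, paths[1])
  wr(ds$blocks, paths[2])
  invisible(paths)
}

#' Read a logger export
#'
#' `native_csv` reads the pair written by [write_logger_export()].
#' `movebank_csv` reads a Movebank-style flat CSV with columns `timestamp`,
#' `individual-local-identifier` and `gls:light-level` (light only; the
#' returned dataset has an empty block table, since Movebank serves the
#' 4-hourly sensors as separate studies).
#'
#' @param path path prefix (native) or file (movebank).
#' @param dialect `"native_csv"` or `"movebank_csv"`.
#' @return A validated [logger_dataset()].
#' @export
read_logger_export <- function(path, dialect = c("native_csv", "movebank_csv")) {
  dialect <- match.arg(dialect)
  parse_t <- function(x) as.POSIXct(x, tz = "UTC",
                                    tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                                   "%Y-%m-%d %H:%M:%OS",
                                                   "%Y-%m-%d %H:%M"))
  if (dialect == "native_csv") {
    paths <- paste0(path, c("_light.csv", "_blocks.csv"))
    if (!all(file.exists(paths))) {
      stop("format error: expected ", paths[1], " and ", paths[2], call. = FALSE)
    }
    rd <- function(p) {
      hdr <- readLines(p, n = 1)
      if (!startsWith(hdr, "# ")) stop("format error: missing metadata line in ", p,
                                       call. = FALSE)
      meta <- jsonlite::fromJSON(sub("^# ", "", hdr))
      df <- utils::read.csv(p, skip = 1, check.names = FALSE)
      list(meta = meta, df = tibble::as_tibble(df))
    }
    li <- rd(paths[1]); bl <- rd(paths[2])
    light <- li$df
    if (!all(c("time", "light") %in% names(light))) {
      stop("format error: light file must have columns time, light", call. = FALSE)
    }
    light$time <- parse_t(light$time)
    blocks <- bl$df
    blocks$block_start <- parse_t(blocks$block_start)
    logger_dataset(
      bird_id = li$meta$bird_id,
      deploy_start = parse_t(li$meta$deploy_start),
      deploy_end = parse_t(li$meta$deploy_end),
      light = light, blocks = blocks,
      clock_drift_corrected = isTRUE(li$meta$clock_drift_corrected)
    )
  } else {
    if (!file.exists(path)) stop("format error: no such file ", path, call. = FALSE)
    df <- utils::read.csv(path, check.names = FALSE)
    need <- c("timestamp", "gls:light-level")
    if (!all(need %in% names(df))) {
      stop("format error: movebank_csv needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    tm <- parse_t(df$timestamp)
    id <- if ("individual-local-identifier" %in% names(df)) {
      as.character(df$`individual-local-identifier`[1])
    } else "unknown"
    logger_dataset(
      bird_id = id,
      deploy_start = min(tm), deploy_end = max(tm) + 300,
      light = tibble::tibble(time = tm, light = as.integer(df$`gls:light-level`)),
      blocks = tibble::tibble(block_start = as.POSIXct(character(), tz = "UTC"),
                              cond_max = integer(), wet_sum = integer(),
                              temp_min = numeric(), temp_mean = numeric(),
                              temp_max = numeric())
    )
  }
}

#' Pipeline configuration
#'
#' All tunable parameters of the analysis in one validated list. Defaults:
#' light threshold 2.5 (2.5% of the 0-100 relative scale); fixed
#' sun-elevation angle -3.5 deg; conductivity class thresholds fresh < 10 <=
#' brackish < 60 <= sea on the 0-127 scale; a block is dry below 5% wet
#' occupancy; migration onset above 3 deg longitude per day; particle model
#' with 500 particles, truncated-lognormal speeds (flight mode 15 m/s max
#' 25, water mode 0.5 m/s max 2), SST tolerance 1 degC, angle band
#' [-7, -1] deg; KDE on a 100-cell-per-axis grid with the ad hoc bandwidth
#' and 25/50/75% contours.
#'
#' @param ... overrides of the defaults (partial matching not used).
#' @return A classed list (`pipeline_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    light_threshold = 2.5,
    light_scale_max = 100,
    sun_angle_mode = "fixed",
    fixed_angle = -3.5,
    c_fresh_brackish = 10,
    c_brackish_sea = 60,
    wet_fraction_dry_threshold = 0.05,
    migration_rate_deg_per_day = 3,
    migration_min_run = 1,
    migration_exit_deg = 5,
    lon_stable_deg = 2,
    wintering_range_deg = 10,
    prebreeding_range_deg = 15,
    stationary_min_days = 10,
    n_particles = 500,
    twilight_err_sd_min = 4,
    angle_band = c(-7, -1),
    speed_dry_mode_ms = 15, speed_dry_max_ms = 25,
    speed_wet_mode_ms = 0.5, speed_wet_max_ms = 2,
    speed_sdlog = 0.6,
    sst_tolerance = 1,
    conductivity_mode = "hard",
    conductivity_soft_weight = 0.1,
    polar_lon_sd_deg = 2,
    prior_lat_sd_deg = 1.5,
    kde_grid_cells = 100,
    kde_bandwidth = "adhoc",
    kde_levels = c(25, 50, 75),
    kde_projection = "aeqd",
    clock_drift_corrected = TRUE,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  if (!(cfg$c_fresh_brackish >= 0 && cfg$c_fresh_brackish < cfg$c_brackish_sea &&
        cfg$c_brackish_sea <= 127)) {
    stop("need 0 <= c_fresh_brackish < c_brackish_sea <= 127", call. = FALSE)
  }
  if (!all(cfg$kde_levels > 0 & cfg$kde_levels < 100)) {
    stop("kde_levels must lie in (0, 100)", call. = FALSE)
  }
  if (cfg$n_particles < 1) stop("n_particles must be >= 1", call. = FALSE)
  if (!cfg$conductivity_mode %in% c("hard", "soft", "off")) {
    stop("conductivity_mode must be hard, soft or off", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read/write a pipeline configuration as YAML
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()` the
#'   path, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                           digits = NA)), tf)
  unname(tools::md5sum(tf))
}

#' Write pipeline results to disk
#'
#' Positions and tracks go to CSV (`bird_id`, `twilight_time`, `lon`, `lat`,
#' `method`, flags), stage segmentations to CSV intervals, utilization
#' contours to GeoJSON polygons, the phenology table to CSV, and a JSON
#' manifest lists every file together with an MD5 hash of the configuration.
#'
#' @param results named list holding at least one of `positions`, `track`
#'   (a `duck_track`), `stages` (a `stage_segmentation`), `phenology`,
#'   `uds` (named list of `duck_ud`).
#' @param out_dir output directory, created if needed.
#' @param config the `pipeline_config` used (hashed into the manifest).
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(results, out_dir, config = pipeline_config()) {
  known <- c("positions", "track", "stages", "phenology", "uds")
  if (!is.list(results) || !any(known %in% names(results))) {
    stop("results must contain at least one of ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create ", out_dir, call. = FALSE)
  }
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, name)
  }
  if (!is.null(results$positions)) emit(results$positions, "positions.csv")
  if (!is.null(results$track)) emit(generics::tidy(results$track), "track.csv")
  if (!is.null(results$stages)) {
    emit(generics::tidy(results$stages), "stages.csv")
    sp <- results$stages$stopovers
    if (!is.null(sp) && nrow(sp) > 0) emit(sp, "stopovers.csv")
  }
  if (!is.null(results$phenology)) emit(results$phenology, "phenology.csv")
  if (!is.null(results$uds)) {
    for (nm in names(results$uds)) {
      ud <- results$uds[[nm]]
      gj <- ud_contours_geojson(ud, levels = attr(ud, "levels") %||% c(25, 50, 75))
      p <- file.path(out_dir, paste0("ud_", nm, ".geojson"))
      writeLines(gj, p)
      files <- c(files, basename(p))
    }
  }
  manifest <- list(
    files = files,
    config_hash = config_hash(config),
    package = "ducktrack",
    version = as.character(utils::packageVersion("ducktrack")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           pretty = TRUE)),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Tagging and recovery rates
#'
#' Cohort bookkeeping: the recapture rate, the resighted rate (recaptured
#' plus identified-but-not-recaptured birds) and the logger's maximum share
#' of body mass, all in percent.
#'
#' @param n_deployed birds tagged (default 48).
#' @param n_recaptured loggers recovered (default 19).
#' @param n_resighted_only birds identified but not recaptured (default 9).
#' @param logger_mass_g logger mass in grams (default 3.3).
#' @param body_mass_min_g lightest body mass in grams (default 580).
#' @return One-row tibble with `recapture_rate_pct`, `resighted_rate_pct`,
#'   `logger_mass_fraction_pct`.
#' @examples
#' tagging_summary()
#' @export
tagging_summary <- function(n_deployed = 48, n_recaptured = 19,
                            n_resighted_only = 9, logger_mass_g = 3.3,
                            body_mass_min_g = 580) {
  tibble::tibble(
    recapture_rate_pct = 100 * n_recaptured / n_deployed,
    resighted_rate_pct = 100 * (n_recaptured + n_resighted_only) / n_deployed,
    logger_mass_fraction_pct = 100 * logger_mass_g / body_mass_min_g
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
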