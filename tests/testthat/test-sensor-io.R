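make_dataset <- function() {
  t0 <- as.POSIXct("2017-07-01 00:00:00", tz = "UTC")
  logger_dataset(
    bird_id = "BG001",
    deploy_start = t0, deploy_end = t0 + 2 * 86400,
    light = tibble::tibble(time = t0 + seq(0, 2 * 86400 - 300, 300),
                           light = rep(c(0L, 50L), length.out = 576)),
    blocks = tibble::tibble(
      block_start = t0 + seq(0, 2 * 86400 - 14400, 14400),
      cond_max = c(3L, 5L, 90L, 95L, 30L, 0L, 12L, 8L, 100L, 60L, 2L, 1L),
      wet_sum = c(480L, 240L, 480L, 0L, 100L, 480L, 480L, 30L, 470L, 480L, 0L, 12L),
      temp_min = rep(3, 12), temp_mean = rep(4, 12), temp_max = rep(5.5, 12)
    )
  )
}

test_that("native export round-trips field-for-field", {
  ds <- make_dataset()
  pre <- file.path(tempdir(), "bird_bg001")
  write_logger_export(ds, pre)
  back <- read_logger_export(pre, "native_csv")
  expect_equal(back$bird_id, ds$bird_id)
  expect_equal(back$deploy_start, ds$deploy_start)
  expect_equal(back$deploy_end, ds$deploy_end)
  expect_equal(back$light$time, ds$light$time)
  expect_equal(back$light$light, ds$light$light)
  expect_equal(as.data.frame(back$blocks), as.data.frame(ds$blocks))
})

test_that("a 3-row hand-written fixture parses to its literal contents", {
  lp <- file.path(tempdir(), "tiny_light.csv")
  bp <- file.path(tempdir(), "tiny_blocks.csv")
  writeLines(c(
    '# {"bird_id":"X1","deploy_start":"2017-07-01T00:00:00Z","deploy_end":"2017-07-01T00:15:00Z","clock_drift_corrected":true}',
    "time,light",
    "2017-07-01T00:00:00Z,0",
    "2017-07-01T00:05:00Z,17",
    "2017-07-01T00:10:00Z,64"), lp)
  writeLines(c(
    '# {"bird_id":"X1","deploy_start":"2017-07-01T00:00:00Z","deploy_end":"2017-07-01T00:15:00Z","clock_drift_corrected":true}',
    "block_start,cond_max,wet_sum,temp_min,temp_mean,temp_max",
    "2017-07-01T00:00:00Z,12,480,3.5,4.25,5"), bp)
  ds <- read_logger_export(file.path(tempdir(), "tiny"), "native_csv")
  expect_equal(ds$bird_id, "X1")
  expect_equal(ds$light$light, c(0L, 17L, 64L))
  expect_equal(ds$light$time[2],
               as.POSIXct("2017-07-01 00:05:00", tz = "UTC"))
  expect_equal(ds$blocks$cond_max, 12L)
  expect_equal(ds$blocks$temp_mean, 4.25)
})

test_that("out-of-range and non-monotonic records are rejected with row context", {
  ds <- make_dataset()
  bad <- ds$blocks
  bad$cond_max[3] <- 200L
  expect_error(logger_dataset("B", ds$deploy_start, ds$deploy_end,
                              ds$light, bad),
               "0-127.*block 3")
  badl <- ds$light
  badl$time[5] <- badl$time[3]
  expect_error(logger_dataset("B", ds$deploy_start, ds$deploy_end,
                              badl, ds$blocks),
               "non-monotonic.*row 5")
  badw <- ds$blocks
  badw$wet_sum[2] <- 900L
  expect_error(logger_dataset("B", ds$deploy_start, ds$deploy_end,
                              ds$light, badw),
               "0-480")
})

test_that("movebank dialect maps timestamp and light columns", {
  p <- file.path(tempdir(), "mb.csv")
  writeLines(c(
    'timestamp,individual-local-identifier,gls:light-level',
    "2017-07-01 00:00:00.000,BG007,1",
    "2017-07-01 00:05:00.000,BG007,23"), p)
  ds <- read_logger_export(p, "movebank_csv")
  expect_equal(ds$bird_id, "BG007")
  expect_equal(ds$light$light, c(1L, 23L))
  expect_equal(nrow(ds$blocks), 0)
  expect_error(read_logger_export(file.path(tempdir(), "absent.csv"),
                                  "movebank_csv"), "format error")
})

test_that("write_outputs produces files, valid GeoJSON and a config-hashed manifest", {
  set.seed(5)
  pts <- data.frame(lon = rnorm(300, 20, 1), lat = rnorm(300, 57, 0.5))
  ud <- kernel_ud(pts)
  out <- file.path(tempdir(), "outdir")
  cfg <- pipeline_config()
  man <- write_outputs(list(positions = tibble::tibble(
    bird_id = "B", twilight_time = Sys.time(), lon = 1, lat = 2,
    method = "fixed", lat_flag = "ok"
  ), uds = list(winter = ud)), out, config = cfg)
  expect_true(file.exists(file.path(out, "positions.csv")))
  gj <- jsonlite::fromJSON(file.path(out, "ud_winter.geojson"),
                           simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_gt(length(gj$features), 0)
  expect_equal(gj$features[[1]]$geometry$type, "Polygon")
  # manifest hash changes iff the configuration changes
  man2 <- write_outputs(list(uds = list(winter = ud)), out, config = cfg)
  expect_equal(man$config_hash, man2$config_hash)
  man3 <- write_outputs(list(uds = list(winter = ud)), out,
                        config = pipeline_config(n_particles = 777))
  expect_false(man3$config_hash == man$config_hash)
  # empty results are an error, not an empty manifest
  expect_error(write_outputs(list(), out), "at least one")
})

test_that("config validation enforces threshold ordering and YAML round-trip", {
  expect_error(pipeline_config(c_fresh_brackish = 80, c_brackish_sea = 60),
               "c_fresh_brackish")
  expect_error(pipeline_config(kde_levels = c(0, 50)), "kde_levels")
  expect_error(pipeline_config(nonsense = 1), "unknown config")
  cfg <- pipeline_config(n_particles = 123, angle_band = c(-6, -2))
  p <- file.path(tempdir(), "cfg.yaml")
  write_config(cfg, p)
  back <- read_config(p)
  expect_equal(back$n_particles, 123)
  expect_equal(back$angle_band, c(-6, -2))
})
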