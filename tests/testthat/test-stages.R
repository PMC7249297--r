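# Hand-built daily series: the segmentation rules are exercised directly on
# constructed summaries, independently of the simulator.
daily_series <- function(lon, wet_class, polar = FALSE,
                         start = as.Date("2017-06-20")) {
  n <- length(lon)
  tibble::tibble(
    date = start + seq_len(n) - 1, lon = lon, lon_inherited = FALSE,
    polar = rep_len(polar, n), wet_class = rep_len(wet_class, n),
    all_fresh_dry = rep_len(wet_class, n) %in% c("fresh", NA),
    n_blocks = 6L
  )
}

test_that("constant longitude on fresh water is one breeding interval", {
  d <- daily_series(lon = rep(48.8, 120), wet_class = "fresh")
  seg <- segment_annual_cycle(d, bird_id = "X")
  expect_equal(nrow(seg$intervals), 1)
  expect_equal(seg$intervals$label, "breeding")
  expect_equal(seg$intervals$start, d$date[1])
  expect_equal(seg$intervals$end, d$date[120] + 1)
})

test_that("3-degree day jitter inside an 8-degree range stays one wintering interval", {
  set.seed(12)
  lon <- c(rep(48.8, 30), seq(48, 22, length.out = 4),
           21 + pmin(pmax(rnorm(120, 0, 3), -4), 4))
  wc <- c(rep("fresh", 30), rep("sea", 4), rep("brackish", 120))
  d <- daily_series(lon, wc)
  seg <- segment_annual_cycle(d, bird_id = "J")
  iv <- seg$intervals
  expect_equal(sum(iv$label == "wintering"), 1)
  expect_equal(sum(iv$label == "spring_migration"), 0)
  expect_equal(max(iv$end), d$date[nrow(d)] + 1)
})

test_that("water types missing on >20% of days raise a segmentation error", {
  d <- daily_series(rep(48.8, 100), "fresh")
  d$wet_class[1:30] <- NA
  d$all_fresh_dry[1:30] <- NA
  d$n_blocks[1:30] <- 0L
  expect_error(segment_annual_cycle(d), "20%")
})

test_that("every deployment day belongs to exactly one interval", {
  set.seed(2)
  ch <- default_cohort(n_birds = 1, seed = 2)
  w <- default_world()
  ds <- simulate_logger(ch$scenarios[[1]], w, seed = 90)
  res <- analyze_logger(ds, w, start_lon = ch$design$breeding_lon,
                        start_lat = ch$design$breeding_lat, prob_track = FALSE)
  iv <- res$segmentation$intervals
  expect_equal(iv$start[-1], iv$end[-nrow(iv)])
  expect_equal(sum(iv$n_days), as.numeric(max(iv$end) - min(iv$start)))
})

test_that("segmentation is idempotent and invariant to a +10 deg longitude shift", {
  set.seed(12)
  lon <- c(rep(48.8, 40), seq(47, 23, length.out = 3), rep(21, 60) + rnorm(60))
  wc <- c(rep("fresh", 40), rep("sea", 3), rep("brackish", 60))
  d <- daily_series(lon, wc)
  s1 <- segment_annual_cycle(d)
  s2 <- segment_annual_cycle(s1$daily)
  expect_equal(s1$intervals, s2$intervals)
  d10 <- d
  d10$lon <- d10$lon + 10
  s3 <- segment_annual_cycle(d10)
  expect_equal(s3$intervals$label, s1$intervals$label)
  expect_equal(s3$intervals$start, s1$intervals$start)
  expect_equal(s3$intervals$mean_lon, s1$intervals$mean_lon + 10)
})

test_that("stopovers follow the >=2-day rule and White Sea labelling", {
  # breeding (fresh), marine post-moult at 49, travel, 3-day pause at 38 E,
  # travel, wintering at 21
  lon <- c(rep(49, 30), rep(49, 10), 43, rep(38, 3), 30, rep(21, 40) + 0.1)
  wc <- c(rep("fresh", 30), rep("sea", 15), rep("brackish", 40))
  d <- daily_series(lon, wc)
  seg <- detect_stopovers(segment_annual_cycle(d))
  expect_equal(seg$intervals$label[1:4],
               c("breeding", "post_moult", "autumn_migration", "wintering"))
  so <- seg$stopovers
  expect_equal(nrow(so), 1)
  expect_equal(so$n_days, 3)
  expect_true(so$white_sea) # 38 E lies in the 33.9-41.6 E band
  expect_lt(abs(so$mean_lon - 38), 0.5)

  # a 1.5-day pause (one stationary day) is below the two-day rule
  lon2 <- c(rep(49, 30), rep(49, 10), 43, 38, 30, rep(21, 40) + 0.1)
  wc2 <- c(rep("fresh", 30), rep("sea", 13), rep("brackish", 40))
  seg2 <- detect_stopovers(segment_annual_cycle(daily_series(lon2, wc2)))
  expect_equal(nrow(seg2$stopovers), 0)
})

test_that("migration distance obeys its closed-form and degenerate contracts", {
  d0 <- Sys.Date()
  tr <- data.frame(date = d0 + 0:1, lon = c(0, 1), lat = c(0, 0))
  expect_lt(abs(migration_distance(tr, d0, d0 + 2, min_step_km = 0,
                                   pad_days = 0) - 111.2), 0.1)
  co <- data.frame(date = d0 + 0:1, lon = c(5, 5), lat = c(50, 50))
  expect_equal(migration_distance(co, d0, d0 + 2, min_step_km = 0,
                                  pad_days = 0), 0)
  one <- data.frame(date = d0, lon = 5, lat = 50)
  expect_true(is.na(migration_distance(one, d0, d0 + 2)))
})

test_that("phenology summaries compute Table-style statistics", {
  mk <- function(id, pm_start, pm_dur) {
    iv <- tibble::tibble(
      label = c("breeding", "post_moult", "autumn_migration", "wintering"),
      start = as.Date(c("2017-06-20", pm_start,
                        as.character(as.Date(pm_start) + pm_dur),
                        as.character(as.Date(pm_start) + pm_dur + 3))),
      end = as.Date(c(pm_start, as.character(as.Date(pm_start) + pm_dur),
                      as.character(as.Date(pm_start) + pm_dur + 3),
                      "2018-05-17")),
      mean_lon = c(49, 49, 35, 21), sd_lon = 0.5
    )
    iv$n_days <- as.numeric(iv$end - iv$start)
    structure(list(intervals = iv, stopovers = NULL, daily = NULL,
                   bird_id = id), class = "stage_segmentation")
  }
  # two birds with post-moult durations 30 and 36 days
  ph <- phenology_summary(list(mk("A", "2017-09-10", 30),
                               mk("B", "2017-09-14", 36)))
  row <- ph[ph$stage == "post_moult" & ph$statistic == "duration_days", ]
  expect_equal(row$value, 33)
  expect_equal(row$sd, sd(c(30, 36)))
  expect_equal(row$min, "30"); expect_equal(row$max, "36")
  expect_equal(row$n, 2L)
  srow <- ph[ph$stage == "post_moult" & ph$statistic == "start", ]
  expect_equal(srow$mean, "2017-09-12")
  # a single bird: SD empty, range collapses to the value
  ph1 <- phenology_summary(list(mk("A", "2017-09-10", 30)))
  r1 <- ph1[ph1$stage == "post_moult" & ph1$statistic == "duration_days", ]
  expect_true(is.na(r1$sd))
  expect_equal(r1$min, r1$max)
})
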