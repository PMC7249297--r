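make_day_light <- function(lon = 20, lat = 57.5, date = "2017-12-01") {
  noisefree_light(lon, lat, date, as.Date(date) + 10)
}

test_that("noise-free crossings match the brute-force solar oracle", {
  li <- make_day_light()
  tw <- detect_twilights(li, threshold = 2.5, site_lon = 20)
  d <- as.Date("2017-12-03")
  det_rise <- tw$time[tw$kind == "sunrise" & as.Date(tw$time) == d][1]
  det_set <- tw$time[tw$kind == "sunset" & as.Date(tw$time) == d][1]
  # light was generated so the 2.5% threshold sits at -3.5 deg elevation
  or_rise <- oracle_crossing(20, 57.5, d, -3.5, "rise")
  or_set <- oracle_crossing(20, 57.5, d, -3.5, "set")
  expect_lt(abs(as.numeric(det_rise) - as.numeric(or_rise)), 5 * 60)
  expect_lt(abs(as.numeric(det_set) - as.numeric(or_set)), 5 * 60)
})

test_that("twilight pair count equals days with a day/night cycle", {
  li <- make_day_light()
  tw <- validate_twilights(detect_twilights(li, 2.5, site_lon = 20),
                           quiet = TRUE)
  n_days <- length(unique(as.Date(li$time)))
  n_rise <- sum(tw$kind == "sunrise")
  # every full simulated day has exactly one sunrise (edges may clip one)
  expect_gte(n_rise, n_days - 2)
  expect_lte(n_rise, n_days)
})

test_that("constant bright light yields a polar-day pair at estimated midnight", {
  tm <- as.POSIXct("2017-06-21", tz = "UTC") + seq(0, 3 * 86400 - 300, 300)
  li <- tibble::tibble(time = tm, light = 80L)
  tw <- detect_twilights(li, 2.5, site_lon = 48.848)
  expect_true(all(tw$polar_day))
  expect_equal(nrow(tw), 6) # a sunrise+sunset pair per day
  per_day <- split(tw, as.Date(tw$time))
  for (d in per_day) {
    expect_setequal(d$kind, c("sunrise", "sunset"))
    expect_equal(d$time[1], d$time[2]) # both at the same midnight
  }
  # flat light has no usable dip, so midnight comes from the site longitude:
  # solar midnight for 48.8 E is near 20:45 UTC
  hr <- as.numeric(format(tw$time[1], "%H")) + as.numeric(format(tw$time[1], "%M")) / 60
  expect_lt(abs(hr - 20.75), 0.75)
})

test_that("polar-day midnight follows the light-curve dip when present", {
  li <- noisefree_light(48.8, 69.2, "2017-06-18", "2017-06-24")
  tw <- detect_twilights(li, 2.5, site_lon = 10) # wrong site lon on purpose
  expect_true(any(tw$polar_day))
  # midnight must come from the light minimum (true lon 48.8), not site_lon
  pos <- positions_from_twilights(tw, angle = -3.5)
  expect_lt(max(abs(pos$lon - 48.8)), 6)
})

test_that("night-time shading dips are flagged ambiguous", {
  li <- make_day_light()
  # carve three artificial dips below threshold into one night
  night <- which(as.Date(li$time) == as.Date("2017-12-04") &
                   format(li$time, "%H") %in% c("18", "19", "20"))
  li$light[night] <- 40L
  li$light[night[c(10, 11, 20, 21, 30, 31)]] <- 0L
  tw <- detect_twilights(li, 2.5, site_lon = 20)
  d4 <- tw[as.Date(tw$time) == as.Date("2017-12-04"), ]
  expect_gt(sum(d4$quality == "ambiguous"), 0)
  # validated record keeps at most one sunrise and one sunset that day
  ok <- validate_twilights(tw, quiet = TRUE)
  ok4 <- ok[as.Date(ok$time) == as.Date("2017-12-04"), ]
  expect_lte(sum(ok4$kind == "sunset"), 1)
})

test_that("detection is invariant to a common offset of light and threshold", {
  li <- make_day_light()
  tw1 <- detect_twilights(li, 2.5, site_lon = 20)
  li2 <- li
  li2$light <- li2$light + 7L
  tw2 <- detect_twilights(li2, 2.5 + 7, site_lon = 20)
  expect_equal(tw1$time, tw2$time)
  expect_equal(tw1$kind, tw2$kind)
})

test_that("a threshold above the observed light range raises a calibration error", {
  li <- make_day_light()
  expect_error(detect_twilights(li, threshold = 500), "calibration error")
})

test_that("validate_twilights honours identity, degenerate and override contracts", {
  li <- make_day_light()
  tw <- detect_twilights(li, 2.5, site_lon = 20)
  clean <- tw[tw$quality == "ok", ]
  expect_equal(validate_twilights(clean, quiet = TRUE), clean)

  allbad <- clean
  allbad$quality <- "ambiguous"
  expect_warning(out <- validate_twilights(allbad, quiet = TRUE),
                 "all twilight events removed")
  expect_equal(nrow(out), 0)
  expect_equal(nrow(positions_from_twilights(out, angle = -3.5)), 0)

  ov <- tibble::tibble(time = allbad$time[3], action = "keep")
  kept <- validate_twilights(allbad, overrides = ov, quiet = TRUE)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$time, allbad$time[3])
})
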