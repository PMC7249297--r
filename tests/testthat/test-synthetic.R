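test_that("a stationary stage stays within 3 step-SDs of its anchor", {
  w <- default_world()
  sc <- stationary_scenario(20, 57.5, "2017-11-01", "2017-12-15")
  tr <- simulate_track(sc, w, seed = 3, step_sd_km = 15)
  d <- haversine_km(tr$lon, tr$lat, 20, 57.5)
  expect_lt(max(d), 3 * 15 * sqrt(2) + 1e-6) # 3 SD per axis, diagonal bound
  expect_gt(mean(d), 1) # and it does move
})

test_that("identical seeds give identical tracks, different seeds differ", {
  w <- default_world()
  sc <- stationary_scenario(20, 57.5, "2017-11-01", "2017-11-20")
  t1 <- simulate_track(sc, w, seed = 9)
  t2 <- simulate_track(sc, w, seed = 9)
  t3 <- simulate_track(sc, w, seed = 10)
  expect_identical(t1, t2)
  expect_false(identical(t1$lon, t3$lon))
})

test_that("a speed-specified migration leg derives its duration from the route", {
  # anchors ~1200 km apart at 60 km/h: leg under 2 days
  w <- default_world()
  stages <- tibble::tibble(
    label = c("post_moult", "autumn_migration", "wintering"),
    start = as.Date(c("2017-10-01", "2017-10-10", NA)),
    end = as.Date(c("2017-10-10", NA, "2017-11-10")),
    lon = c(49, NA, 30), lat = c(70.6, NA, 62),
    speed_kmh = c(NA, 60, NA)
  )
  sc <- track_scenario(stages)
  mig <- sc$stages[sc$stages$label == "autumn_migration", ]
  dist <- haversine_km(49, 70.6, 30, 62)
  expect_gt(dist, 1000)
  expect_lte(as.numeric(mig$end - mig$start), 2)
})

test_that("anchors outside the world raise a scenario error", {
  w <- default_world()
  sc <- stationary_scenario(150, 57.5, "2017-11-01", "2017-11-20")
  expect_error(simulate_track(sc, w, seed = 1), "outside world bounds")
})

test_that("scenario stages must be contiguous and ordered", {
  expect_error(track_scenario(tibble::tibble(
    label = c("breeding", "wintering"),
    start = as.Date(c("2017-06-20", "2017-10-01")),
    end = as.Date(c("2017-09-01", "2018-05-01")),
    lon = c(48, 20), lat = c(69, 57)
  )), "contiguous")
})

test_that("noise-free light crosses the threshold at the scripted sun angle", {
  li <- noisefree_light(20, 57.5, "2017-12-01", "2017-12-04", sun_angle = -3.5)
  tw <- detect_twilights(li, 2.5, site_lon = 20)
  el <- solar_position(tw$time, 20, 57.5)$elevation
  expect_lt(max(abs(el - (-3.5))), 0.3)
})

test_that("polar-day light never crosses the threshold", {
  li <- noisefree_light(48.8, 69.1, "2017-06-20", "2017-06-27")
  expect_true(all(li$light > 2.5))
})

test_that("heavier shading biases summer latitude toward the equator", {
  w <- default_world()
  sc <- stationary_scenario(20, 57.5, "2018-06-01", "2018-06-20")
  tr <- simulate_track(sc, w, seed = 4, step_sd_km = 0.001)
  lat_for <- function(p) {
    li <- simulate_light(tr, shading = list(p_shade = p, depth_meanlog = 1,
                                            depth_sdlog = 0.5), seed = 6)
    tw <- validate_twilights(detect_twilights(li, 2.5, site_lon = 20),
                             quiet = TRUE)
    pos <- positions_from_twilights(tw, angle = -3.5, lat_hint = 57.5)
    mean(pos$lat[pos$lat_flag == "ok"], na.rm = TRUE)
  }
  expect_lt(lat_for(0.85), lat_for(0))
})

test_that("sensor blocks reflect construction: wet sums, conductivity, SST", {
  w <- default_world()
  sc <- stationary_scenario(20, 57.5, "2017-11-01", "2017-11-15")
  tr <- simulate_track(sc, w, seed = 5)
  tr$wet <- TRUE
  bl <- simulate_blocks(tr, w, params = list(temp_sd = 0), seed = 6)
  expect_true(all(bl$wet_sum == 480))
  expect_true(all(bl$cond_max >= 0 & bl$cond_max <= 127))
  expect_true(all(bl$temp_min <= bl$temp_mean & bl$temp_mean <= bl$temp_max))
  # fully wet, zero noise: logger temperature equals the SST field
  sst <- w$sst(20, 57.5, bl$block_start)
  expect_lt(max(abs(bl$temp_mean - sst)), 0.3) # walk moves the bird slightly
  # fully dry block: wet_sum 0 and dry conductivity
  tr$wet <- FALSE
  bl0 <- simulate_blocks(tr, w, seed = 7)
  expect_true(all(bl0$wet_sum == 0))
  expect_true(all(classify_water_type(bl0) == "dry"))
})

test_that("conductivity classes track the scripted water type in >=95% of blocks", {
  w <- default_world()
  ch <- default_cohort(n_birds = 2, seed = 3, world = w)
  for (b in 1:2) {
    tr <- simulate_track(ch$scenarios[[b]], w, seed = 40 + b)
    bl <- simulate_blocks(tr, w, seed = 50 + b)
    cls <- classify_water_type(bl)
    want <- c(land_fresh = "fresh", brackish_sea = "brackish",
              open_sea = "sea")[bl$water_type]
    agree <- cls == want | cls == "dry"
    expect_gt(mean(agree), 0.95)
  }
})

test_that("truth positions stay in water-type-consistent cells per stage", {
  w <- default_world()
  ch <- default_cohort(n_birds = 4, seed = 8, world = w)
  for (b in 1:4) {
    tr <- simulate_track(ch$scenarios[[b]], w, seed = 60 + b)
    expect_true(all(tr$water_type[tr$stage == "breeding"] == "land_fresh"))
    expect_true(all(tr$water_type[tr$stage == "wintering"] %in%
                      c("brackish_sea", "open_sea")))
    expect_true(all(tr$water_type[tr$stage == "post_moult"] == "open_sea"))
    expect_true(all(tr$water_type[tr$stage == "pre_breeding"] == "open_sea"))
  }
})

test_that("the synthetic SST field matches its documented closed form", {
  d <- as.Date("2018-02-01")
  doy <- as.numeric(format(d, "%j"))
  lat <- c(55, 60, 65, 70)
  expect_equal(
    synthetic_sst(20, lat, d),
    pmax(8 - 0.35 * (lat - 55) +
           pmax(7 - 0.25 * (lat - 55), 0) * cos(2 * pi * (doy - 215) / 365.25),
         -1)
  )
})
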