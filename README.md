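# ducktrack

Year-round light-level geolocation for Arctic sea ducks carrying archival
loggers that record, besides light, water conductivity, wet/dry state and
temperature.

## The problem

Small archival geolocators (GLS) give at most two positions per day from
sunrise and sunset times: longitude from the timing of local noon, latitude
from day length at a calibrated sun-elevation angle. Around the equinoxes
day length carries no latitude information, and under 24-h polar daylight
there are no twilights at all — yet for an Arctic-breeding sea duck the key
annual-cycle transitions (departure from the tundra, autumn migration into
a wintering basin, spring return) happen exactly then. The loggers'
auxiliary channels rescue the analysis: the conductivity maximum separates
freshwater, brackish and marine water on a relative 0–127 scale, the
wet/dry sum (0–480 per 4-h block) separates swimming from flight, and
logger temperature can be matched against sea-surface temperature.

ducktrack implements the full pipeline for such records:

* twilight detection and automated validation (equinox and polar-day
  handling included), `detect_twilights()` / `validate_twilights()`;
* threshold positioning with three calibration schemes — known-site
  ("rooftop"), fixed angle (−3.5°), and Hill–Ekstrom (minimum latitude
  variance over a stationary winter window);
* a particle-filter track model, `run_prob_track()`, combining twilight
  geometry with per-pair sun-angle sampling, movement feasibility (flight
  vs swim speeds chosen from the wet/dry record), land/ice exclusion, an
  SST likelihood, and a **conductivity/water-type likelihood** that pins a
  wintering bird into a brackish basin that temperature alone cannot
  distinguish from the open sea in winter;
* rule-based segmentation of the annual cycle into six staging periods
  (breeding, post-moult, autumn migration, wintering, spring migration,
  pre-breeding) with stopover detection and phenology tables;
* kernel utilization distributions with the classical ad hoc bandwidth
  `h = sqrt((var_x + var_y)/2) · n^(−1/6)` and 25/50/75% mass contours;
* a synthetic-bird generator (scripted itineraries over an abstract
  Barents/Baltic-like world with forward-modelled sensors) so the whole
  pipeline is testable without field data.

Everything is tidyverse-shaped: tibbles in and out, `tidy()`/`glance()`
methods on fitted objects, `autoplot()` for each result type.

## Worked example

Simulate one default bird, run the standard analysis, and look at the
recovered annual cycle:

```r
library(ducktrack)

world  <- default_world()
cohort <- default_cohort(n_birds = 1, seed = 5, world = world)
bird   <- cohort$design[1, ]

logger <- simulate_logger(cohort$scenarios[[1]], world, seed = 105)
logger
#> <logger_dataset> bird SB001
#>   deployment: 2017-06-17 to 2018-06-19 UTC
#>   light samples: 105696 ( 0 gaps )
#>   sensor blocks: 2202

result <- analyze_logger(logger, world,
                         start_lon = bird$breeding_lon,
                         start_lat = bird$breeding_lat, seed = 205)
result$segmentation
#> <stage_segmentation> bird SB001
#> # A tibble: 7 x 6
#>   label            start      end        n_days mean_lon  sd_lon
#>   <chr>            <date>     <date>      <dbl>    <dbl>   <dbl>
#> 1 breeding         2017-06-17 2017-09-27    102     49.1  1.02
#> 2 post_moult       2017-09-27 2017-10-17     20     48.5  0.390
#> 3 autumn_migration 2017-10-17 2017-10-20      3     25.8  9.18
#> 4 wintering        2017-10-20 2018-05-25    217     18.6  0.459
#> 5 spring_migration 2018-05-25 2018-05-26      1     44.2 NA
#> 6 pre_breeding     2018-05-26 2018-06-14     19     44.6  1.05
#> 7 breeding         2018-06-14 2018-06-19      5     48.9  0.0701
```

The bird breeds on tundra lakes near 49° E, moves to sea in late September,
makes a three-day autumn dash to the brackish wintering basin near 19° E,
stays 217 days, and returns through a coastal pre-breeding stage — each
boundary recovered within a couple of days of the scripted truth (the
scripted wintering onset for this bird is 2017-10-19). The particle track
behind it:

```r
glance(result$track)
#> # A tibble: 1 x 6
#>   n_pairs n_particles conductivity mean_ess min_ess  seed
#>     <int>       <dbl> <chr>           <dbl>   <dbl> <dbl>
#> 1     656         500 hard             59.1    1.63   205
```

Phenology rows (here a single bird, so SDs are empty and ranges collapse):

```r
phenology_summary(list(result$segmentation),
                  tracks = setNames(list(result$track), bird$bird_id))
#>              stage     statistic  mean    value  n
#>       post_moult duration_days      20   20.000  1
#> autumn_migration duration_days       3    3.000  1
#>        wintering duration_days     217  217.000  1
#> autumn_migration   distance_km  2082.5 2082.521  1
#> ...
```

Study bookkeeping (cohort counts and logger mass as inputs):

```r
tagging_summary()
#> # A tibble: 1 x 3
#>   recapture_rate_pct resighted_rate_pct logger_mass_fraction_pct
#>                <dbl>              <dbl>                    <dbl>
#> 1               39.6               58.3                    0.569
```

`autoplot()` works on tracks, segmentations, calibrations and utilization
distributions; `write_outputs()` serialises positions, stages, phenology
and UD contours (GeoJSON) with a config-hashed manifest.

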