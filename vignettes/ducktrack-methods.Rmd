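---
title: "Methods: year-round geolocation of sea ducks from light, conductivity and temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: year-round geolocation of sea ducks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ducktrack analyses archival geolocator (GLS) records from sea ducks across a
full annual cycle. The loggers considered here store relative light (maximum
per 5 minutes), and per 4-hour block a conductivity maximum (relative
0-127 scale), a wet/dry sum (0-480, from 30-s sampling) and temperature
statistics. From these the package reconstructs positions, an annual-cycle
segmentation into six staging periods, phenology tables and space-use
surfaces. This vignette explains the models, their assumptions, the defaults
and the numerical choices.

## Threshold geolocation

A light threshold (default 2.5% of the logger scale) defines twilights:
linearly interpolated crossings of the 5-minute light series. Because each
stored sample is the *maximum* of five one-minute readings, a rising light
curve's stored value equals its newest minute while a falling curve's equals
its oldest; uncorrected, sunrises are detected about four minutes early.
`detect_twilights()` shifts rising crossings by `pooling_window_min - 1`
minutes to undo this exactly for monotone light.

Each consecutive sunrise/sunset pair yields one position. Longitude comes
from the pair midpoint (local solar noon or midnight versus UTC, 15 degrees
per hour, with the equation-of-time correction). Latitude solves the sunrise
equation so that the modelled time above the calibrated sun-elevation angle
matches the observed day (or night) length. We invert in closed form:
writing the sunrise equation as `A sin(lat) + B cos(lat) = sin(angle)` with
`A = sin(dec)` and `B = cos(dec) cos(HA)`, the solutions are
`asin(C/R) - phi` and `180 - asin(C/R) - phi` with `R = sqrt(A^2 + B^2)`,
`phi = atan2(B, A)`. This is exact and vectorises over particle clouds,
which is why we prefer it to a numerical root search; the two roots are the
genuine hemisphere alias (two latitudes share any given day length). A
`lat_hint` (deployment site, or each particle's previous position) selects
the root; without a hint an ambiguous pair is flagged, never guessed.
Near the equinoxes day length carries no latitude information: pairs whose
day length admits no root in [-85, 85] degrees, or whose best root mismatches
the observed day length by more than 10 minutes, are flagged
`equinox_undefined` with `lat = NA` (never a placeholder value).

During polar day there are no crossings. The detector then emits a
sunrise+sunset pair at the estimated local solar midnight. Where the 24-h
light curve shows a usable dip (the sun is lowest at local midnight), the
midnight is the centre of the minimum plateau of a 2-h-smoothed light curve;
this is what makes longitudes available at all during the polar summer,
at much reduced accuracy (roughly +-10 degrees under shading). Without a
usable dip the midnight comes from the median pair longitude of the
preceding week, falling back to the deployment site.

Quality control emulates "unequivocal" manual screening with two automatic
rules: same-kind crossings within 4 h keep the earliest sunset / latest
sunrise and flag the rest; adjacent opposite-kind crossings closer than 1 h
(a physically implausible night or day, the signature of a shading dip) are
both flagged. `validate_twilights()` drops flagged events and applies an
optional per-event override list.

## Sun-elevation calibrations

* **Known site** (`calibrate_known_site()`): the median geometric solar
  elevation at the detected crossings, evaluated at the known location;
  requires twilights on at least 7 days.
* **Fixed angle**: the configured `fixed_angle` (default -3.5 degrees, a
  conventional value for Northern Hemisphere sea ducks; rooftop
  calibrations tend to sit lower because they lack plumage shading).
* **Hill-Ekstrom** (`calibrate_hill_ekstrom()`): over a stationary winter
  window (>= 30 days, away from equinoxes), the angle in a -10..0 degree
  grid (step 0.25) minimising the variance of the latitude series. At the
  true angle the latitudes are flattest; any other angle imprints the
  seasonal declination trend. The full variance-versus-angle profile is
  returned and plotted by `autoplot()`.

## The particle track model

`run_prob_track()` is a forward particle filter over twilight pairs,
initialised at the tagging location. Per pair and particle:

1. twilight-time errors (Gaussian, default SD 4 min) and a sun-elevation
   angle (uniform over the configured band, default [-7, -1] degrees, which
   brackets the calibration ranges typical of this logger type) produce a
   candidate position through the threshold geometry; where latitude is
   undefined (equinox, polar day) it is drawn from the movement prior
   around the particle's previous position, with a spread tied to the
   current speed regime's reach;
2. candidates on ice are rejected, as are candidates on land while the
   logger is wet (fresh-water blocks permit land cells, where the lakes
   are);
3. movement feasibility weights each candidate by a truncated-lognormal
   likelihood on the implied speed. The regime comes from the wet/dry
   record *between* the twilights: any dry block means flight (mode 15 m/s,
   max 25), otherwise swim/drift (mode 0.5 m/s, max 2). Using the
   between-twilight record matters: a bird that flew overnight and then sat
   on water must be judged by flight speeds;
4. when the bird was wet outside fresh water, a Gaussian SST weight
   (SD = `sst_tolerance`, default 1 degC against a stated logger accuracy
   of 0.5 degC) compares logger temperature with the SST field;
5. the conductivity extension weights candidates by agreement between the
   logger's water-type class and the world's class at the candidate. The
   class is the modal non-dry class of the between-twilight blocks, which
   keeps a single misread conductivity block (a ~1% event under the
   generator's noise) from vetoing a whole pair. The default is a hard mask
   (`conductivity_mode = "hard"`); a soft down-weight and "off" (the base
   model) are exposed because the original lab calibration behind the
   thresholds is not published. Class thresholds default to fresh < 10 <=
   brackish < 60 <= sea on the relative 0-127 scale, and a block is dry
   below 5% wet occupancy;
6. systematic resampling keeps `n_particles` (default 500) particles. If
   every particle is rejected the pair is retried with a graded escape:
   the measurement proposal widens (capped at 4x), then the speed ceiling
   relaxes, then latitude is treated as missing, and finally the hard mask
   degrades to the soft weight; a hard error is raised only after
   `max_retries` failures.

The reported track is the weighted geographic median of each pair's cloud
(spherical Weiszfeld iteration; the two-point tie-break is the geodesic
midpoint), with the per-pair chosen angle, the effective sample size and
the movement regime. `basin_occupancy()` pools retained clouds over a date
window and reports water-class fractions - the diagnostic behind the
conductivity extension.

Water type, not temperature, is what separates a brackish from a marine
basin in winter: the synthetic SST field is built so that its north-south
contrast nearly vanishes in winter (as it does between the real Baltic and
the subarctic seas), so the SST term cannot resolve the basins then.

## Annual-cycle segmentation

`segment_annual_cycle()` is a deterministic forward-scanning rule set over
daily summaries (median pair longitude per day, modal water-type class,
fresh-or-dry flags). The deployment opens in breeding. Post-moult starts at
the first modal-marine day or a sustained 3-day-median longitude shift
beyond 5 degrees (15 degrees where the recent days are polar-flagged, since
polar longitudes are far noisier). Migrations start at the first of two
consecutive days displaced more than `migration_exit_deg` (5 degrees) from
the running median of the current stationary stage - a band-exit rule that
is immune to day-to-day jitter inside the stage's longitudinal range (the
wintering rule tolerates < 10 degrees of total range). Wintering starts on
the first day whose displacement has settled below 3 degrees/day and from
which the next 10 days stay within 10 degrees with an unchanged modal water
class; stopover pauses, at most a week, never satisfy this. Spring
migration ends symmetrically with the constancy window widened to
15 degrees (polar-day inaccuracy), and breeding resumes after three
consecutive modal-fresh days. We deliberately scan *forward* for arrivals
so that recovered boundaries land on the transition day instead of lagging
by a trailing-window length. An override table can pin any onset per bird.

Stopovers are maximal runs of >= 2 days inside a migration interval whose
longitudes stay within `lon_stable_deg` (2 degrees); each reports its mean
longitude and whether it falls in the White Sea band (33.9-41.6 degrees E).

`migration_distance()` measures the great-circle path length through daily
median positions. Two numerical choices matter and are exposed as
arguments: steps below `min_step_km` (75 km, far above position scatter and
far below a real migration-day displacement for this species) count as
zero, because twice-daily scatter at a multi-day stopover otherwise adds
hundreds of spurious kilometres; and when the track carries movement
regimes, only water-contact positions serve as waypoints, because
threshold positions taken mid-flight are systematically distorted (the
within-pair longitude change smears the apparent day length). The interval
is padded by one day (plus two when regime-filtering) so the resting
positions flanking a 1-2-day flight are available. With fewer than two
usable positions the distance is `NA`, never zero.

`phenology_summary()` reports per-stage start/end/duration (mean, sample
SD, range, n), mean longitudes and migration distances across birds. The
breeding duration is "estimated" by folding the second-year breeding onset
back one year against the post-moult onset, since no deployment spans a
full breeding stage.

## Kernel utilization distributions

`kernel_ud()` computes a bivariate normal KDE on a projected plane with the
classical "ad hoc" reference bandwidth `h = sqrt((var_x + var_y)/2) *
n^(-1/6)` (one isotropic h), on a square grid of 100 cells per axis
("100 cells" follows the home-range convention of cells per side) padded by
3h. The default projection is a local azimuthal equidistant about the point
centroid, which treats distances faithfully at these latitudes; a
plate-carree option mirrors a naive lon/lat computation (the difference is
a few percent in contour area at 58 degrees N). Densities are normalised
over the grid; `ud_contour(level)` returns the smallest density-threshold
region holding `level`% of the mass, as polygons in geographic coordinates
(two separated clusters legitimately yield disjoint rings). Identical
points make the reference bandwidth degenerate; the error message suggests
a manual `h`.

## The synthetic-bird generator

The generator exists so that every downstream stage is testable without
field data. It emulates the study conditions of an Arctic-breeding sea duck
cohort:

* an abstract world with a tundra breeding region of freshwater lakes
  around 69.1 N 48.8 E, a brackish Baltic-like basin (lon 14-30,
  lat 54-61.5) with open sea directly to its north, a marine White-Sea-like
  embayment spanning the 33.9-41.6 E band, continental land south and
  east, a documented closed-form SST field (north-south gradient plus a
  latitude-dependent seasonal sinusoid, winter-converging), and ice north
  of 71.5 N from December to April;
* scripted itineraries: deployment ~364 +- 11 days from about 20 June;
  post-moult from 12 Sep +- 11 d lasting 33 +- 10 d at sea; a rapid autumn
  migration (four birds pause at 35/39/38/38 E for 4/7/6/3 days);
  wintering 212 +- 3 d, 18 of 19 birds in the brackish basin and one in
  the embayment; spring migration 2 +- 1 d; a coastal marine pre-breeding
  stage of 23 +- 7 d. These values define the generator's defaults;
  anchor draws are clipped so the 3-step-SD random walk stays inside each
  stage's water-type region;
* movement: stationary stages are a per-axis reflected random walk with a
  15 km/day displacement SD; migrations follow great circles through the
  scripted stopovers, flying hours dry;
* sensors: per-minute light is a logistic function of solar elevation
  scaled so the detection threshold corresponds exactly to the scripted
  sun angle (-3.5 degrees), with per-minute Bernoulli shading (p = 0.3,
  lognormal attenuation depth) and 5-minute max-pooling to the integer
  scale; conductivity draws around water-type levels (dry 1, fresh 3,
  brackish 35, sea 95; SDs 1/3/8/10) clamped to 0-127; the wet sum is
  binomial over the 480 per-block samples; temperature tracks the SST
  field with a dry-fraction air offset.

What the generator does *not* emulate - real coastlines and bathymetry,
tides, weather-driven shading autocorrelation, logger clock drift (assumed
pre-corrected; a config flag records this), individual behavioural
idiosyncrasy - bounds what passing tests show about real data: they
validate the estimators' internal consistency and their behaviour under
geolocator-scale noise, not the field error of any particular deployment.

## Problem sizes, seeds and reproducibility

Package checks run the full 19-bird cohort once (about three minutes),
calibration recoveries on 2-3-month stationary records, and the KDE checks
at n = 10,000 points on a 100x100 grid; these sizes were chosen so every
recovery criterion is measurable at geolocator-scale error (boundaries to
+-2 days, wintering medians to ~100 km, distances to a few percent) while
a full check pass stays comfortably interactive. All stochastic components
(generator, particle filter) take explicit integer seeds; identical seeds
reproduce tracks, clouds and medians exactly.

## Known limitations

* Longitude during polar day depends on the light-curve dip; under heavy
  shading the dip can wander by an hour or more (~15 degrees), and stages
  separated only during polar day inherit this inaccuracy.
* The hemisphere alias is resolved by a hint, which assumes the analyst
  knows the hemisphere; trans-equatorial migrants would need continuity
  logic the package does not implement.
* The conductivity hard mask trusts the world's water-type raster; with a
  coarse or wrong raster the soft mode is the safer choice.
* Daily longitudes inherit the previous day's value when a day has no
  valid pair; long runs of flagged twilights therefore flatten the series
  and can delay migration onsets by a day or two.
* `phenology_summary()` folds breeding duration over exactly 365 days,
  which is a half-day biased in leap years.
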