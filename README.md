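# remcam

Density estimation for unmarked animals from camera-trap data with the
random encounter model (REM), written for wildlife ecologists who have
camera-trap event tables but no individually recognisable animals.

Most camera-trap density methods (spatially explicit capture–recapture)
need marked individuals. The REM instead treats cameras as static detectors
in an ideal gas of movers: animals at density *D* moving at speed *V* past a
detection zone of radius *r* and full angle *θ* generate contacts at rate
*ρ = D·V·r·(2+θ)/π* per camera. Inverting this,

    D̂ = (y/t) · π / (V · r · (2+θ))

where *y* is the number of independent photographic events and *t* the
camera-hours of effort. The estimator's key assumption is that cameras are
placed randomly with respect to animal movement — cameras on shade trees
that attract the study animal during the day violate it, which is why the
package supports day/night, season and habitat stratification to isolate
windows where the assumption approximately holds.

The package covers the full workflow:

* **Event processing** — collapse raw triggers into independent events
  (configurable gap, chained merging), classify the 18:00–06:00 night
  window, stratify effort by habitat polygons, and compute
  ratio-of-totals encounter rates with a camera-level bootstrap
  (`collapse_events`, `camera_tallies`, `bootstrap_rate`).
* **The estimator** — REM density, delta-method variance with per-parameter
  CV² components, lognormal/normal confidence intervals, analytic and
  finite-difference sensitivities (`rem_estimate`, `rem_sensitivity`).
* **Field parameters** — detection-zone radius and angle from approach
  trials (circular bearing means), movement speed from continuous-follow
  logs with pride-level replication (`estimate_detection_zone`,
  `estimate_speed`).
* **Reference densities** — kernel utilization distributions with reference
  bandwidths, 75% isopleth home ranges, habitat overlap, buffer widths from
  mean home-range area, buffered camera-hull effective areas, and census
  densities Σ Nᵢpᵢ/A with buffer-driven CIs (`fit_ud`, `isopleth`,
  `buffer_width`, `effective_area`, `reference_density`).
* **A mechanistic simulator** (Rcpp) — straight-line or correlated-walk
  movers on a torus with exact segment–sector entry detection, plus a
  daytime camera-attraction scenario reproducing placement bias, for
  validating the whole pipeline by parameter recovery
  (`simulate_encounters`, `run_study`).

## Worked example

Simulate a survey over a known world (5 animals/km², 25 cameras, 2000 h),
then recover density from its event table:

```r
library(remcam)

cfg   <- sim_config(arena = c(10, 10), density = 5, n_cameras = 25,
                    duration_h = 2000, seed = 42)
world <- simulate_encounters(cfg)

ind  <- collapse_events(world$events, gap_min = 15)
tal  <- camera_tallies(ind, world$deployments)
rate <- bootstrap_rate(tal, n_boot = 10000, seed = 1)
rate
#> Encounter rate: 0.00982 events/h (y = 491, t = 50000 h)
#>   bootstrap var = 1.45e-07 (n_boot = 10000, seed = 1)

params <- rem_params(V = 0.2, r = 10, theta = 50,
                     r_unit = "m", angle_unit = "degrees")
rem_estimate(rate, params)
#> REM density: 5.37 animals/km^2 (se 0.208, 95% CI 4.977-5.793, lognormal)
```

The 95% interval covers the true density of 5 animals/km². The interval
here reflects only encounter-rate uncertainty; standard errors on *V*, *r*
and *θ* (from `estimate_speed()` / `estimate_detection_zone()`) propagate
through the same call when supplied. Sensitivities confirm where
measurement effort matters:

```r
round(rem_sensitivity(params, "r",     0.01), 1)  #> 1.0   (% change in D)
round(rem_sensitivity(params, "theta", 0.01), 1)  #> 0.3
```

A +1% error in detection radius moves the estimate by 1.0%; the same error
in the detection angle moves it by only 0.3%.

## Acceptance script

`scripts/acceptance.R` recomputes the two headline sensitivity quantities
from scratch by building the parameter set (radius 14.42 m, angle 50.12°)
and running `rem_sensitivity()` on the installed package, writing them as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
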