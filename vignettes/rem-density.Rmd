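---
title: "Estimating animal density from camera-trap encounter rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating animal density from camera-trap encounter rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remcam)
```

## The model

The random encounter model (REM) treats camera traps as static detectors in
an ideal gas of moving animals. An animal moving at speed $V$ sweeps past a
detector whose zone is a sector of radius $r$ and full angle $\theta$; for
animals at density $D$ with isotropic headings, contacts accrue at the rate

$$\rho = \frac{D\,V\,r\,(2+\theta)}{\pi} \quad \text{events per camera-hour,}$$

so density can be recovered from an observed encounter rate $y/t$ ($y$
independent photographic events over $t$ camera-hours):

$$\hat D = \frac{y}{t}\cdot\frac{\pi}{V\,r\,(2+\theta)}.$$

The estimator requires no individual recognition, which is what makes it
attractive for unmarked species. Its load-bearing assumption is that cameras
are placed randomly with respect to animal movement: any feature that draws
animals toward (or repels them from) camera sites biases $y/t$ directly into
$\hat D$. The package exists to compute $\hat D$ with honest uncertainty,
estimate the field parameters $V$, $r$, $\theta$ from trial and follow data,
compare against census-based reference densities, and probe the
random-placement assumption with a mechanistic simulator.

### Elasticities

Because $\hat D \propto V^{-1} r^{-1} (2+\theta)^{-1}$, the proportional
sensitivity of the estimate is $-1$ for speed and radius and
$-\theta/(2+\theta)$ for the angle. At the field-estimated angle of
50.12° this is $-0.304$: a 1% error in the radius moves the estimate by
1.0%, the same error in the angle by only 0.3% (`rem_sensitivity()`).
Measurement effort is therefore best spent on $r$ and $V$.

## Event processing conventions

* **Independent events.** A stationary animal re-triggering a camera is one
  biological contact. Triggers at one camera separated by less than a
  configurable gap (default **15 minutes**) are merged, chained (each trigger
  compared with its predecessor), and stamped with the first trigger's time.
  The field definition — an animal entering and exiting the field of view —
  has no numeric counterpart in the source data, so the gap is an explicit
  analyst's knob, recorded in all provenance output. A merged event keeps the
  largest group count observed in its run.
* **Group handling.** An event contributes 1 to $y$ regardless of how many
  individuals are pictured (`per_individual = FALSE`, the default): groups
  such as lion prides are not cohesive, and treating grouped individuals as
  independent leaves the estimator unbiased while inflating variance. The
  per-individual alternative is available and logged.
* **Night window.** Night is the half-open daily window **[18:00, 06:00)**,
  wrapping midnight; no instant is double-counted. Night effort is 12 h per
  active camera-day (half the deployed hours), which keeps night-only
  encounter rates per night-hour — the convention required for night
  estimates to pair with night-time speeds $V_n$ in $V\,t$.
* **Timestamps** are naive camera-stamped local times; no timezone or DST
  arithmetic is ever applied.

## Variance

Encounter-rate uncertainty is estimated by resampling **camera locations**
with replacement (default 10,000 replicates) and recomputing the
ratio-of-totals rate $\sum y_i / \sum t_i$; spatial heterogeneity among
cameras, not within-camera Poisson noise, dominates. The delta method then
propagates all sources to the density scale. For a product of independent
factors the squared coefficients of variation add, with the angle damped by
its elasticity:

$$\mathrm{CV}^2(\hat D) = \mathrm{CV}^2(y/t) + \mathrm{CV}^2(V) +
  \mathrm{CV}^2(r) + \left(\frac{\theta}{2+\theta}\right)^2\mathrm{CV}^2(\theta).$$

Both pieces are verified against independent oracles in the test suite:
exhaustive enumeration of all $n^n$ resamples on 2–3 camera toy inputs, and a
$10^6$-draw Monte-Carlo propagation of lognormal/normal parameter errors
(agreement within 2% for CVs up to 0.15).

The default 95% interval is lognormal, $\hat D\,\exp(\pm 1.96\sqrt{\ln(1+\mathrm{CV}^2)})$,
which guarantees positive bounds for a positive quantity; the symmetric
normal interval is computed alongside and both are reported. The source
analyses do not state their interval rule, so this was a genuinely open
choice; the lognormal default matters only at large CVs.

## Field parameters

* **Detection zone** (`estimate_detection_zone()`): the radius is the mean
  first-trigger distance of repeated frontal approaches with the standard
  error of that mean; the angle is the circular difference between the
  circular mean bearings of paired left/right perpendicular approaches.
  Circular (unit-vector) means are essential because a compass protocol can
  straddle north — bearings of 335° and 25° must yield 50°, not 310°. The
  angle's SE combines the two mean-bearing SEs in quadrature (the source
  protocol does not say how it combined them; quadrature is this package's
  choice for independent means).
* **Speed** (`estimate_speed()`): follow logs carry odometer distance per
  time segment. Speed is path distance per unit time — odometer semantics,
  not net displacement. Segments straddling 18:00/06:00 are split pro-rata
  by time with distance allocated proportionally. The **pride is the
  sampling unit**: each pride's windowed rate is computed first, and the
  group estimate is the unweighted mean across prides with the SE across
  prides, because hours within a follow are strongly autocorrelated.

## Reference densities

Census knowledge of group sizes provides an independent density to judge the
REM against: $D_{ref} = \sum_i N_i p_i / A$, where $N_i$ is the known female
count of pride $i$, $p_i$ the fraction of its 75% home range inside the
habitat, and $A$ the habitat area effectively sampled.

* **Utilization distributions** are Gaussian-kernel surfaces with one shared
  reference bandwidth $h = \sqrt{(\mathrm{var}(x)+\mathrm{var}(y))/2}\,
  n^{-1/6}$ on a grid of cell edge $h/4$ (cell-size sensitivity on the
  Gaussian test case is below 1%). The 75% home range takes grid cells in
  decreasing density order until 0.75 of the mass is covered.
* **Smoothing bias, stated plainly:** the kernel inflates the spread of the
  fitted surface by $h^2$ per axis, so at $n = 1000$ relocations the expected
  75% area exceeds the true Gaussian value $2\ln(4)\pi\sigma^2$ by a factor
  $\approx 1 + n^{-1/3} = 1.10$. A green recovery test against the
  *smoothing-corrected* closed form establishes the estimator is right; it
  does not make reference-bandwidth areas unbiased at realistic sample
  sizes. With a few dozen relocations per pride (the realistic case) the
  inflation is larger still, which is one reason buffer width — derived from
  these areas — dominates reference-density uncertainty.
* **Buffer width** is "half the mean home-range diameter", operationalised
  as the circular-equivalent radius of the mean area, $w=\sqrt{\bar a/\pi}$.
  This convention reproduces all four published buffer values (4.0, 3.9,
  5.0, 4.1 km) from the published mean areas at one decimal; the
  mean-of-radii alternative is also reported. Confidence limits treat the
  per-pride radii as the sample.
* **Effective area** is the convex hull of the camera locations, Minkowski-
  buffered by $w$ (corner arcs discretised at 1°, an error below $10^{-4}$
  relative), intersected with the habitat polygon. Whether the original
  analysis intersected the buffered hull with the habitat or buffered
  habitat-specific sub-grids separately is not fully stated; intersection is
  used here and logged. Home-range/habitat overlap $p_i$ is evaluated on the
  UD's own equal-area grid cells, which makes the proportions of habitats
  that partition the plane sum to exactly 1.

## The simulator: what it emulates, and what a green test means

`simulate_encounters()` moves point animals at constant speed on a toroidal
arena containing sector detection zones, and emits an event whenever an
animal's path segment enters a zone it was outside of. The torus is chosen
over reflecting walls because it preserves the uniform-density assumption
exactly. Entry detection is **exact segment–sector intersection**, so
straight-line movers have no time-discretisation bias — necessary because the
recovery criterion compares a 200-replicate mean to the closed form within a
~1% band. Defaults are the stated validation world: density 5 animals/km²,
speed 0.2 km/h, radius 10 m, angle 50°, 25 cameras on a grid with random
headings, 2000 h at 1-min steps — parameter scales matching the field system
(lion speeds of 0.13–0.31 km/h, a 14 m/50° zone, ~2.3 km camera spacing).

The **placement-bias scenario** adds daytime attraction: during 06:00–18:00
each free animal is drawn, with probability $q$ per hour (default 0.1), to
the shade tree at its nearest camera — one photographic event is logged there
— and rests for a fixed duration (default 2 h) before resuming its route.
Two design points deserve emphasis:

* *Rest-in-place rather than relocation.* Physically relocating the animal
  to the camera truncates its natural path: the relocated animal starts at
  distance zero from its rest camera and must travel a nearest-neighbour
  spacing before it can encounter another zone, so afternoon attractions
  cast an encounter "shadow" hours into the night and depress night rates by
  roughly 13% at these settings — for grid and random placement alike, and
  worse under a correlated walk (strong turning makes animals linger near
  the rest camera and inflates night rates fourfold instead). That would
  contaminate exactly the window the scenario is supposed to keep clean.
  Modelling the visit as a pause — the lion diverts to a nearby tree, rests,
  and resumes its range use — keeps the night-time spatial distribution
  uniform; the residual night bias is the ~5% due to rests spilling past
  18:00, well inside estimation uncertainty at the tested effort.
* *Entry-event semantics.* An animal must leave a zone before it can trigger
  a new event there, and however long it rests it counts once — matching the
  independent-event definition used on the real data.

What the simulator does **not** emulate: pride cohesion (animals are
independent movers, consistent with how grouped individuals are treated in
estimation), hunting or territorial behaviour, landscape resistance, and
detection failure — every true zone entry is recorded. A green recovery test
therefore establishes that the estimator and its variance machinery are
correct *under the model's own assumptions*; it cannot certify field
performance where those assumptions fail, which is precisely what the
day/night contrast is for.

## Numerical choices

* Gap default 15 min; night window [18:00, 06:00); night effort = half of
  deployed hours.
* KDE bandwidth as above; grid padding 3 bandwidths; isopleth area = cell
  count × cell area.
* Lognormal 95% CI by default; normal optional; both stored.
* Bootstrap default 10,000 replicates; the RNG seed is an explicit argument
  everywhere and recorded in every stochastic output.
* Degrees and metres are converted exactly once, at `rem_params()`
  construction; a radius above 0.5 km passed as "km" is rejected as almost
  certainly metres (unit mistakes must never be silently absorbed).
* Boundary points in point-in-polygon tests count as inside, and a camera on
  a shared habitat edge goes to the first polygon in file order, logged.

## Known limitations

* The independence gap is a surrogate for the original visual judgement of
  stationary animals; results should always be reported with the gap used.
* Car-odometer follow distances measure the observer's path; they are
  treated as the animals' path length, as in the source protocol.
* Reference-bandwidth kernel home ranges are biased upward at small-to-
  moderate relocation counts (see above); buffer-width confidence limits are
  the mechanism that propagates this uncertainty into reference densities.
* Reconstructing published density estimates from published (rounded) survey
  inputs reproduces them only to within ~6% relative error; the residual is
  attributable to unprinted precision in effort and parameter values, and
  the test suite asserts the 6% band rather than forcing equality.
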