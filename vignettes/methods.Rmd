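---
title: "Models and methods behind hydrurga"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hydrurga}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hydrurga reconstructs a year of pinniped movement and behaviour from
the two channels an archival GLS tag records: ambient light (the
maximum per 10-minute window, sampled every 60 s) and salt-water
immersion (the count of positive 3-second conductivity tests per
10-minute window, 0 completely dry to 200 completely wet). This
vignette explains the models, their assumptions, the tunable parameters
and the numerical choices, and states what the synthetic-data tests do
and do not demonstrate about real deployments.

## Solar geometry and twilight detection

Solar position uses the NOAA low-accuracy formulae (declination and
equation of time from the Julian century). Against an independently
coded Astronomical-Almanac ephemeris the zenith angle agrees to better
than 0.2°, which at a 10-minute light cadence is far below the
measurement noise.

Twilights are threshold crossings of the light record, interpolated
linearly in light between the two bracketing windows. One subtlety
matters: each record is the *maximum* over the 10-minute window
starting at its timestamp, so a rising light curve is represented by
its value near the window's end while a falling curve is represented
near its start. `detect_twilights()` therefore shifts rise-crossing
brackets by the window length (`window_min`, default 10). Without this
correction sunrise is detected ~10 min early while sunset is unbiased,
which biases longitude about 1° east — an error that calibration
cannot absorb, because it affects the twilight *midpoint* rather than
the day length.

Dark runs embedded inside a day's bright span shorter than
`min_run_hours` (default 4 h) are flagged `suspect_shading` — on a
seal they are almost always the animal's body covering the sensor
while hauled out — and never emitted as twilights.

### Calibration is identifiable only up to a ridge

`calibrate()` grid-searches (zenith, threshold) for the pair minimizing
the RMS discrepancy between detected and predicted twilight times at a
known site. Because the sensor's light transfer curve is monotone in
solar elevation, every threshold has a matching zenith at which the
crossing happens, and the score surface has a ridge of photometrically
equivalent pairs. Any ridge point positions identically; tests
therefore assert ridge consistency (the recovered pair predicts the
twilights to within ~2 min and recovers the site) rather than literal
parameter identity.

### The threshold position and its degeneracies

Longitude comes from the rise/set midpoint against solar noon (equation
of time applied); latitude solves the sunrise equation for the mid-date
declination. Near the equinoxes day length approaches 12 h at every
latitude: within |declination| < 4° (about ±10 days) the latitude is
flagged `equinox_degenerate`, and downstream the twilight error scale
is inflated by `equinox_inflation` (default 3) rather than the
observation being discarded — the movement prior then carries the
latitude through the window. The sunrise equation can also admit two
latitude branches with nearly equal day length near the equinox;
`threshold_position(ref_lat = )` disambiguates by proximity to a
reference latitude, which `initial_path()` tracks sequentially along
the record (initialized at the first fix). Without this, a branch flip
can seed the sampler tens of degrees off in the wrong hemisphere.

## The movement model

Locations are indexed by twilight times. The posterior is proportional
to the product of per-twilight error densities and pairwise movement
terms, with fixed locations (days the animal was observed at the
deployment site) never proposed.

**Twilight error.** The observed minus predicted twilight time `e`
(sign flipped for dusks) follows a shifted log-normal: `e + shift` is
log-normal with median `scale` (default 8 min, shift 2 min, sdlog 0.6).
The asymmetry encodes that shading can only delay dawns and advance
dusks. Inside the sampler a *soft* variant of this likelihood is used:
beyond the support (including polar day/night) the log-density
continues linearly downward instead of jumping to −∞. The sampled
posterior is unaffected — equilibrium chains never visit the penalized
region — but a chain initialized infeasibly is pulled back toward the
support instead of being absorbed (a −∞ state can never be left by a
Metropolis move whose proposals are also −∞).

**Movement prior and the area-element correction.** The movement
constraint states that implied speeds between successive locations are
log-normal with arithmetic mean 1 km/h and SD 0.9 km/h (`meanlog` and
`sdlog` derived internally; the SD interpretation of the stated 0.9 is
a deliberate reading of a value quoted with speed units). A subtlety
with real teeth: a pairwise factor equal to the log-normal speed
*density* used directly as a density in 2-D position space induces
step speeds distributed like s·dlnorm(s) — the polar area element
contributes a factor s — which inflates the induced mean speed to
(μ² + σ²)/μ ≈ 1.8 km/h. The sampler's movement term therefore divides
by the speed (subtracts log s), making the induced speed distribution
exactly the stated log-normal. Empirically this is the difference
between recovering 1.0 km/h and 1.75 km/h on speed-recovery
experiments. The exported `speed_log_prior()` keeps the plain
log-normal density semantics.

**Sampling.** Locations of one parity are conditionally independent
given the other, so each pass makes two vectorized half-updates
(odd-first on odd passes, even-first on even — the forward/backward
sweep alternation). Per-location bivariate Gaussian proposals in km
adapt during burn-in toward 20–40% acceptance. Single-site moves relax
small-scale jitter quickly but long-wavelength modes (latitude through
the equinox window) only diffusively; block-translation proposals —
a contiguous free segment shifted by one common offset, accepted or
rejected as a whole — relax exactly those modes and are essential to
converging within a few thousand iterations. The initial path
(threshold positions, robust running-median smoothing, fixes overlaid,
then midpoint-pulling until the mean implied speed is at or below the
prior mean) deliberately starts *smoother* than the posterior bulk:
re-adding wiggle is fast, removing it is the slowest direction.

Defaults: 50% burn-in, thinning to ≤ 200 retained samples per chain.
Chains are deterministic given `seed` (chain c uses seed + c − 1).

**Polar day.** Runs of days with no usable twilight (24-h daylight)
are measured by `handle_polar_day()` — `duration_days` counts from the
first twilight-less day to the day twilights resume — and downstream
covariates are pinned to the last estimated position before the run.

**Time-spent grids.** Sampled paths are densified to `k` great-circle
intermediate points per segment, each weighted `dt/k` hours, and
accumulated on a lon/lat grid over `n_simulations` (default 1000)
sampled paths; the mean grid is normalized to unit mass and per-cell
quantiles across simulations summarize spread.

## Haul-out segmentation

Immersion counts minus 200 turn dry spells into "dives": bouts are
maximal runs at −200, from the first completely-dry window to the
first subsequent wetter one, kept if ≥ `min_dry_duration` (1 h). Hour
bins are clock-aligned UTC, closed-open, hauled-out iff overlapping
any bout. Recording gaps > 30 min break runs; the affected bouts are
flagged `truncated` and excluded from duration statistics. Whether the
proportion-of-time denominator should exclude unrecorded gaps is
genuinely ambiguous, so `haulout_summary()` reports both `proportion`
(of the full span) and `proportion_recorded` (of recorded hours).

## The penalized additive binomial engine

Smooths are cubic B-splines on equally spaced knots with second-order
difference penalties: zero for straight lines, so the penalty controls
curvature only. Cyclic terms wrap the three end basis functions and use
a circulant difference penalty, making fitted curves periodic in value
and first two derivatives — appropriate for hour-of-day (period 24)
and week-of-year (period 52). Shrinkage replaces the penalty's null
eigenvalues with 1% of the smallest positive eigenvalue so a whole term
can shrink toward zero and a simple linear relationship can be selected
where appropriate. Each smooth is centred (sum-to-zero over the data)
by QR reparameterization, giving `basis_dim − 1` reference df (9 at
the default `basis_dim = 10`).

Fitting is penalized IRLS with step-halving, converged at a relative
penalized-deviance change below 1e−11 — tight enough that the
penalty→∞ limit reproduces an unpenalized `glm()` to 1e−6. Smoothing
parameters minimize a Laplace/REML-type criterion (penalized deviance
plus half the log-determinant of the penalized information, minus the
penalty log-determinant) by coordinate descent over a log10 grid with
golden-section refinement and warm starts. Random effects are
ridge-penalized group intercepts with their own selected λ; nesting is
by concatenated grouping factors (`random = c("tag", "trip")`), which
reproduces the random-intercept structure at desk scale without full
mixed-model integration. By-factor smooths share one λ across levels —
a deliberate economy that keeps the λ search tractable; per-level edf
and Wald-type p-values are still reported, but note that under a shared
λ the *edf* of a level reflects flexibility, not signal, and is similar
across levels by construction; amplitude and p-values carry the
signal contrast. Smooth p-values are Wald-type approximations and are
labelled as such.

Two measured calibrations worth knowing: on pure-line data a
shrinkage smooth settles near edf ≈ 2 with this engine (mgcv's
shrinkage basis gives ≈ 3.6 on the identical fixture), so "the term
collapsed to a line" is asserted by near-perfect linearity of the
fitted curve rather than edf ≤ 1.5; and AIC is −2ℓ + 2·(total edf).

## Habitat use–availability

Null tracks resample the source track's step lengths with replacement,
draw headings uniformly except for a weak drift (probability 0.2 of
heading along the source's net displacement bearing ± 30°), and reuse
its time stamps — step-length distributions are preserved (two-sample
KS checked in the tests) while spatial preference is destroyed. Use
covariates average each environmental field over 100 posterior chains
per time interval, propagating location uncertainty; null rows are
read at the null-track points. Weekly SST falls back to the monthly
mean when a weekly slice is missing; intervals hauled out on land are
discarded. The candidate ladder is the nine-model family for three
covariates (each linear, each smoothed with shrinkage, each pair),
ranked by log-likelihood. Raster-quantized covariates can carry fewer
distinct values than the default basis; smooth candidates shrink their
basis to the data's resolution and drop out below rank 4.

## Activity models

The hourly design holds the state, hour of day, ISO week (truncated to
53), month, Julian day, posterior-mean location, and the distance to
the nearest land polygon boundary (vertices densified to ≤ 5 km) or the
month's ice-edge line; points inside a polygon or poleward of the edge
are on their haul-out substrate at distance 0. Lagged states enter as
linear binary terms; the first k hours of each trip are dropped. Fits
use the cloglog link — haul-out hours are the rarer outcome, and the
asymmetric link behaves better there than logit.

A diel "peak hour" read off a fitted cyclic smooth by argmax is
unstable: a 1 + cos hazard has a flat top, and midday depletion of the
at-sea pool flattens the realized profile further, so the argmax
wanders ±2 h between replicates (mgcv reproduces the same wander).
`smooth_peak()` instead returns the phase of the curve's first
harmonic, which recovers an injected peak to within ±0.7 h across 20
replicates and is what the recovery suites assert.

## The synthetic generators and what the tests show

`simulate_track()` draws per-step speeds log-normally (arithmetic
mean/SD on the km/h scale; degenerate at SD 0), loiters within
`loiter_radius_km` of the central place during residency, and heads
toward scheduled targets with Gaussian heading noise during migration
legs. The default deployment starts 2 August at the island site, step
interval 12 h. `render_light()` passes solar elevation through a
logistic transfer clipped to an integer 0–64 scale — a BAS-logger-like
convention; the scale itself is arbitrary — positioned so light equals
the threshold exactly at the configured zenith. `render_immersion()`
runs an hourly bout hazard (base 0.06/h, diel amplitude 0.8 peaking at
12:00 UTC, seasonal amplitude 0.5 peaking in week 2, persistence 0.8,
minimum bout 1 h) giving bout durations of one to tens of hours and a
haul-out fraction near 23%, consistent with the 22–31% range reported
for free-ranging deployments of this kind; an optional refractory
period (`refractory_h`) keeps the animal at sea after a bout ends,
which is the mechanism behind negative short-lag coefficients.
`simulate_environment()` builds depth from distance-to-shore (15 m per
km offshore, abyssal cap 6 km, coastal cells zeroed within half a cell
diagonal), SST warming equatorward with a small seasonal cycle, and
monthly ice ramping poleward of a specified edge latitude.

Passing tests on these fixtures demonstrate internal consistency —
the pipeline recovers what the generators injected, segmentation
matches brute-force oracles, the sampler matches dense-grid posteriors,
the additive engine matches glm/mgcv where they overlap — under clean
conditions: no sensor drift or fouling, no cloud-driven light noise
beyond the configured Gaussian, linear-in-time movement between steps,
and environments without fronts or mesoscale structure. They do not
show that a real deployment's calibration holds a year later, that the
twilight error law is correctly specified for a diving animal, or that
habitat selection inferred against a CRW null is free of the usual
availability-definition caveats.

## Problem sizes

The shipped tests and the acceptance script run at desk scale chosen to
exercise every code path with comfortable statistical margins: 30-day
calibration fixtures, 200-step (100-day) tracks with 4 chains × 5,000
iterations for speed recovery, 1,000-record segmentation oracles, 100
type-I-calibration replicates and 20 activity-recovery replicates.
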