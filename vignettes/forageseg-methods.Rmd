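---
title: "Methods: detecting environmentally driven sexual segregation in tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting environmentally driven sexual segregation in tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

forageseg analyses GPS tracks of central-place foraging seabirds — built
around Cory's shearwaters breeding on Berlenga Island (39°23'N, 9°36'W) —
to ask whether the two sexes segregate in where and how they forage, and
whether that segregation sharpens when environmental conditions are poor.
This vignette explains each stage of the pipeline, the assumptions behind
it, the tunable parameters, and what the synthetic data generator does and
does not emulate.

## Trip processing

Tracks arrive as timestamped longitude/latitude fixes (nominally every 5
minutes). A bird's track is split into foraging trips at crossings of a
2-km radius around the colony; the radius is not a biological constant but
a segmentation choice — 2 km excludes rafting birds near the island while
keeping the first and last at-sea fixes. Fixes are projected onto a Lambert
azimuthal equal-area plane centred on the colony. The projection uses the
Gaussian mean radius of curvature at the colony latitude, which keeps
planar distances within 0.5% of WGS84 geodesics out to roughly 1000 km —
ample for trips that top out near 900 km. Reported quantities that are
distances (maximum range, distance to colony) always use WGS84 geodesics;
the planar coordinates exist only for the FPT and kernel machinery, where
a Euclidean metric is required.

Per-fix speed is the geodesic step distance over the elapsed time. Fixes
slower than 3 km/h are classified as resting on the water (drift is below
this; flight is well above it) and removed before first-passage-time
analysis, because drifting bouts otherwise masquerade as intense
small-scale search. The resting mask is retained so time budgets are still
computed on the full trip.

Two numerical choices matter here:

* **Active time.** Removing resting fixes leaves their clock time in the
  record. FPT is a time-based statistic, so a six-hour rest would register
  as six hours of "passage" at a point — precisely the artefact the
  removal is meant to prevent. The moving-only trip therefore carries an
  *active-time* axis in which each resting gap is compressed — but never
  below the time the bird would need to cover the bout's net drift at its
  median moving speed, since a 10-km drift compressed to one fix interval
  would register as implausibly *fast* passage instead. FPT uses active
  time; zone entry/exit times are reported on the clock axis.
* **Interpolation.** The moving path is re-sampled every 0.1 km along the
  path (piecewise linear, timestamps interpolated within segments), so
  that FPT is evaluated on an equidistant path rather than at raw fixes
  whose spacing varies with speed.

Trip metrics are the stage's summary: duration (days), maximum geodesic
distance from the colony (km), the long-trip/short-trip class (LT when
duration ≥ 5 days, otherwise ST — the boundary gap between 4 and 5 days is
assigned to ST), hours flying per day (speed ≥ 3 km/h), and the
percentage of trip time in area-restricted search (below).

## First passage time and ARS zones

The first passage time at a path location is the time taken to cross a
circle of radius $r$ centred there — the interval between the backward and
forward first crossings, each interpolated linearly between the bracketing
path points. Where the path never leaves the circle in one direction
(track ends), FPT is undefined and excluded rather than imputed.

The spectrum of $\mathrm{var}(\log \mathrm{FPT})$ across radii identifies
the spatial scale of area-restricted search: commuting flight yields small,
nearly constant FPT; search behaviour yields large, variable FPT, and the
variance peaks near the scale of the searched patches. The log transform
makes the variance independent of the mean's magnitude. Two radius presets
mirror the two natural scales of these data: a whole-trip pass (radii 1–50
km in 1-km steps, evaluated every 1 km of path) and a fine pass (0.1–10 km
in 0.1-km steps, every 0.1 km). The ARS scale $r^*$ is the radius of the
global variance maximum; a flat spectrum (peak below 0.01) means no
detectable ARS, and ties resolve to the smaller radius. Radii with fewer
than five defined FPT values are dropped from the spectrum.

Labelling needs a cutoff that the variance-peak construction does not
supply. A location is ARS-labelled when its FPT at $r^*$ exceeds the
trip-level mean of defined FPT values — deterministic and scale-free —
and maximal runs of at least 10 consecutive labelled locations (1 km at
the 0.1-km step) become ARS zones, suppressing single-point artefacts.
Labels map back to the original fixes by nearest position along the path;
resting fixes inherit the label of the nearest moving fix in time, which
is where the bird sat down. Percent time in ARS is then a clock-time
budget over all fixes.

Two intrinsic artefacts are worth knowing about. FPT circles that span the
turnaround of an out-and-back commute see both passes, so even a searchless
trip can show a weak large-radius variance peak and a few percent of
labelled time. And each zone carries an elevated-FPT halo of width about
$r^*$ into the adjacent commute, which biases the measured percent time in
ARS upward on trips whose total extent is only a few patch radii. Both
effects are visible in the package's tests and bounded there.

## Kernel overlap and the randomization null

Space-use overlap between sexes is computed per year from ARS locations.
Densities are Gaussian kernel estimates evaluated in the projected plane
(a Gaussian kernel on raw degrees is distorted at this latitude) and
normalized on a regular 0.05° grid, the resolution of the environmental
fields. The bandwidth minimizes the exact least-squares cross-validation
score on a log-spaced candidate grid around the bivariate normal-reference
value; the first dataset's bandwidth is cached and reused for every other
group/year so that overlap differences are not bandwidth differences.

Contours are the smallest set of highest-density cells reaching the target
probability mass (50% core area, 95% home range, 99%); they are nested by
construction. Overlap uses the utilization-distribution overlap index
(UDOI): the area of the union of the two level masks times the integral of
the density product over that union. UDOI equals 1 for two identical
uniform distributions and can exceed 1 for strongly overlapping nonuniform
ones — the reason it is the right index here is that observed randomized
overlaps exceed 1, which bounded indices cannot produce.

The significance of segregation comes from a label randomization: bird
identities are reshuffled between the two groups, all of a bird's
locations moving together (trips are nested within birds; shuffling trips
independently would fake replication), and the overlap recomputed — by
default 1000 times, 200 in the scaled-down test configurations. The
P-value is the tie-inclusive proportion of randomized overlaps at or below
the observed one, $(1 + \#\{perm \le obs\})/(1 + n_{perm})$, which is
bounded away from 0 and equals 1 when every permutation ties. With few
birds the null distribution is discrete and the attainable minimum P is
limited by the number of distinct bird partitions — the demo
configurations keep at least 3 birds per group for this reason.

## Environmental fields

Gridded fields (SST in °C, chlorophyll-a in mg m⁻³, bathymetry as water
depth in m) live on regular lon/lat grids with plain-text ESRI-ASCII I/O.
Composites are per-cell means ignoring missing values. Spatial gradients
use the proportional-change statistic: over each 3×3 moving window,
$(\max - \min) \times 100 / \max$, in percent — an indicator of fronts
(SST, CHL) and slope (bathymetry). The window shrinks at grid edges rather
than dropping the border. The formula divides by the window maximum, so it
is applied to depth magnitude for bathymetry and returns missing where the
window maximum is not positive. SST anomalies subtract a baseline raster;
the baseline defaults to the multi-year mean over the years in the run
configuration, a choice the configuration can override since no single
baseline period is canonical. Regional summaries average cells within a
great-circle buffer of the colony (default 200 km, configurable because
narrower coastal buffers are also in use). The winter NAO index enters
only as a per-year scalar covariate.

## Isotopic niche

Plasma δ¹³C and δ¹⁵N (‰) index foraging habitat (inshore–offshore) and
trophic level. Niche width is the standard ellipse area: with sample
covariance eigenvalues $\lambda_1, \lambda_2$,
$\mathrm{SEA} = \pi\sqrt{\lambda_1 \lambda_2}$ — the 1-SD ellipse holding
about 40% of the probability mass — with the small-sample correction
$\mathrm{SEAc} = \mathrm{SEA}\,(n-1)/(n-2)$. The Bayesian version draws
the covariance from its posterior under a conjugate
normal–inverse-Wishart model with a vague prior (prior df 3, prior scale
$10^{-3} I$, prior mean weight $10^{-3}$); conjugacy gives exact posterior
sampling with no MCMC tuning, 10⁴ draws by default. Posterior medians are
reported (posterior summaries of a right-skewed area are better located by
the median). Niche-size comparisons use the fraction of paired posterior
draws in which one group's ellipse is smaller, with ties split evenly.

## Body condition

Structural size is PC1 of the standardized wing/tarsus/culmen/gonys
matrix — the correlation matrix, because the measurements span different
magnitudes — with the sign fixed so larger wings score larger. The body
condition index (BCI) is the residual, in grams, of capture mass regressed
on PC1, pooled across sexes and years: a single size–mass line keeps BCI
comparable across strata, at the cost that only *contrasts* between
strata are identified (residuals centre on zero overall). Mass gain per
day at sea is (recapture − capture)/trip duration.

## Habitat models

The response is log FPT duration (hours, active time) at sampled ARS
locations — a proxy of search effort. Covariates are bathymetry and its
gradient, SST, SST gradient and anomaly, CHL and its gradient, and
distance to colony. Before fitting, an iterative Spearman screen drops,
from each pair with $|\rho| > 0.5$, the member whose univariate smooth has
the higher AIC. Models are Gaussian additive models: univariate smooths
with at most 5 knots (to limit over-fitting), an optional isotropic
thin-plate smooth of the projected coordinates for residual spatial trend,
and a per-bird random intercept expressed as a penalized ridge term inside
the same additive framework (`s(bird_id, bs = "re")` in mgcv), so one
estimation path covers fixed, random and smooth terms. Smoothing
parameters come from generalized cross-validation. Separate models are fit
per sex.

Candidate structures are ranked by AICc, $AIC + 2k(k+1)/(n-k-1)$ with $k$
the effective number of parameters (total effective degrees of freedom of
the fit, including the scale parameter — the standard accounting for
penalized smooths); Akaike weights and a ΔAICc < 2 top set are reported.
Backwards selection uses bird-stratified k-fold cross-validation (default
5 folds; a bird's rows never straddle the split, and the random intercept
is excluded when predicting held-out birds): the term whose removal least
harms the out-of-fold squared error is dropped while the harm stays within
one standard error of the per-fold differences, floored at 2% of the
current error. The floor is the parsimony rule — smooths that GCV has
already shrunk to nothing change the error by ±fractions of a percent, and
without the floor their retention is a coin flip.

## The synthetic generator

No tracking data ship with the package; the generator produces data with
the statistical structure the pipeline measures, parameterized per sex ×
year stratum with the published six-season summary values as defaults
(sample sizes, trip duration, maximum range, long:short trip ratio,
percent time in ARS, isotope means and ellipse areas, condition offsets,
mass gain; years 2010/2011/2013 are the poor regime, 2012/2014/2015 the
good one, with the winter NAO scalar per year).

A trip is a correlated random walk built from a drawn (duration, range,
percent-ARS) triple. Durations come from a two-component mixture — short
trips on [0.2, 5) days, long on [5, ∞), with the long-trip weight set from
the stratum's LT:ST ratio — and a location shift solved numerically
(uniroot on the truncated-normal mixture mean) so the mixture reproduces
the stratum's mean duration exactly. For some strata the printed ratio and
mean are mutually inconsistent (the implied long-trip share forces a
higher mean than printed); there the weight is reduced instead,
prioritizing the duration mean. The 0.2-day truncation exists because the
printed standard deviations would otherwise allow negative durations.
Ranges scale with the drawn duration ($d_{max} \propto D$), which keeps
the required commuting speed a per-stratum constant and the stratum mean
range unbiased; the price is a trip-level range spread wider than the
printed one — matching both is physically impossible when short trips
cannot reach 800 km (the generator's own feasibility check errors when the
required speed exceeds twice the commuting speed). Duration–range
correlation is therefore induced, not matched.

Movement: commuting legs steer toward waypoints at 35 km/h ground speed
with wrapped-Cauchy heading noise (concentration 0.9, deviations clamped
to ±60° — the distribution's heavy tail would otherwise produce
back-tracking kinks that register as spurious small-scale ARS). Patches
are searched with a centre-attracted wrapped-Cauchy walk (concentration
0.3, speed 8 km/h, attraction weight $(d/r_p)^2$): search effort
concentrates where prey density peaks, the walk stays tethered to the
patch, and — the property the validation relies on — the variance-of-log-
FPT peak then recovers the patch scale, which pure boundary-reflected
walks overshoot toward the patch diameter. Patch residency alternates
30-minute search-flight bouts with 45-minute sitting bouts, and total
patch residency implements the drawn percent-time-in-ARS. Remaining time
is spent loafing on the water at waypoints placed laterally off the
commute axis and pushed clear of every patch's elevated-FPT halo; drift
during any resting bout follows the current heading slowly, so resuming
flight leaves no kink. Patch radii shrink on short trips (capped at a
quarter of the range) so a patch cannot span the whole trip.

Isotopes are bivariate normal draws whose standard-ellipse area equals the
configured value (isotropic unless a covariance is supplied).
Morphometrics derive from one latent size factor; capture mass is linear
in size plus the stratum condition offset, and recapture mass adds the
stratum mass-gain rate times a drawn trip duration. Because the configured
condition offsets are sub-gram while size explains tens of grams,
measurement noise on the morphometrics leaks structural variance into the
mass residuals; the default measurement noise is kept small (a fifth of
realistic field precision) so the offsets are identifiable — with
realistic measurement error, offsets this small would be unrecoverable,
which is itself worth knowing when interpreting published condition
indices. Environmental fields are smoothed white noise plus an
onshore–offshore trend keyed to distance from the colony (SST decreasing
offshore in the default, CHL strictly positive and decaying offshore, and
a depth ramp).

Everything is a pure function of (parameters, configuration, seed):
per-trip seeds are split deterministically from the configuration seed, so
any trip can be regenerated in isolation and full runs are byte-identical
on rerun.

What the generator does *not* emulate: wind and current drift on flight
paths, diving, prey capture, device failure and fix loss, tidal or diel
rhythm in behaviour, and any correlation structure beyond what the
movement model induces. Passing tests therefore show that the measurement
chain recovers known structure of this class — not that it is robust to
every artefact of real logger data.

## Problem sizes and validation design

The test suite and the acceptance script run scaled-down versions of each
experiment, sized so the full suite completes in a few minutes on one
core: 50 seeds for ARS-scale recovery with single-patch trials whose
search effort scales with patch area (constant effort per unit area —
uniform prey density — so different patch sizes are searched to equal
intensity); 100 synthetic null datasets at 200 permutations for the
randomization calibration; 200 trips / 200 isotope samples / 100 birds per
group for stratum parameter recovery; and 12 full-FPT trips for the
percent-time-in-ARS chain. The end-to-end demonstration uses the 2013 and
2015 strata (one poor, one good regime) at a fifth to a quarter of the
published sample sizes.

## Known limitations

* Percent time in ARS is biased upward by several points on strata
  dominated by sub-day trips, where patch halos and loafing overlap
  geometrically; the recovery checks use strata whose printed duration and
  trip-ratio values are mutually consistent.
* Time spent flying per day is reported but not matched by the generator:
  the printed flying hours, ranges and durations jointly over-determine
  the commuting speed, and the generator resolves the conflict in favour
  of range and duration.
* The habitat-model stage reproduces the ranking/deviance machinery
  (AICc, weights, explained deviance, response curves); published
  per-term coefficient tables from mixed smooth models are not
  reconstructable and are out of scope.
* A single global variance peak per trip is used; secondary peaks (nested
  ARS scales) are visible in the spectrum output but not labelled.
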