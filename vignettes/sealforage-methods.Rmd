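---
title: "Methods behind sealforage: from raw biologging records to sex-specific foraging strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind sealforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealforage)
```

`sealforage` implements a complete analysis chain for satellite-telemetry
and time-depth-recorder (TDR) deployments on a sexually dimorphic,
wide-ranging pinniped such as the northern elephant seal: track
filtering and smoothing, dive detection and classification, trip-level
foraging variables, bioenergetic foraging success, multivariate strategy
clustering, spatial niche overlap, and attribution of stopped
transmitters to mechanical failure versus at-sea death. Because raw
field data of this kind are rarely shareable, the package pairs every
analysis stage with a seeded synthetic-data generator that produces
cohorts with the statistical structure the analysis assumes, retaining
full ground truth so that the chain can be validated by recovery.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the limits of what the synthetic
validation can show.

## Track processing

**Speed–distance–angle filter.** Raw ARGOS fixes carry class-dependent
error (location classes 3, 2, 1, 0, A, B) and occasional gross outliers.
The filter removes an interior fix when the implied great-circle speed
to *both* neighbours exceeds `max_speed_kmh` (default 12 km h⁻¹), or
when the fix forms a spike: an inner turning angle below `min_angle_deg`
(default 160°) with both adjacent displacements beyond what the animal
covers at the maximum speed. The thresholds follow standard practice for
elephant-seal telemetry. Where ARGOS supplies an alternate (mirror)
position, it replaces a rejected fix if it satisfies the same criteria.
Published descriptions of this filter leave open whether the angle
criterion applies to one or both adjacent segments; we apply the
conjunction (both segments implausible), which is the conservative
choice — it can only retain more data. A final forward pass guarantees
the postcondition that no retained consecutive pair implies a speed
above the threshold, which a purely local spike test cannot promise when
outliers cluster.

**Continuous-time correlated random walk smoother.** Filtered fixes are
irregular in time; the analysis needs hourly positions. We model each
planar coordinate as integrated Ornstein–Uhlenbeck velocity — velocity
reverts to zero at rate β (h⁻¹) with diffusion σ — observed with
Gaussian error whose standard deviation is set per location class
(defaults 0.25, 0.5, 1.5, 4, 6, 10 km for classes 3…B). β and σ are
fitted per deployment by maximum likelihood through the Kalman filter;
an RTS smoother then yields positions and positional standard deviations
on the hour. The state space is planar: we project into an azimuthal
equidistant plane centred on the colony, which keeps radial distances
exact and planar distortion negligible at trip scale, and report all
distances geodesically after back-projection. When the likelihood
optimisation fails the smoother falls back to piecewise-linear
interpolation with a warning. In the noise-free limit the smoother
reproduces hourly input positions to well under a metre, and on
simulated OU-velocity tracks observed with class-B noise it beats linear
interpolation in RMSE — both are tested.

Repeat deployments of the same female are reduced to one trip per
animal. We retain the first trip deterministically (a seeded random
choice is available) so that reruns are bit-identical.

## Dive processing

Depth series sampled at 1–8 s are subsampled to 8 s, zero-offset
corrected, segmented into dives, and classified.

**Zero-offset correction.** Pressure transducers drift; a slow offset of
the apparent surface corrupts the fixed 15 m retention rule. We estimate
the surface as the 2nd percentile of depth within a rolling 2 h window
and subtract it. The window is long against a dive cycle (~25 min) and
short against sensor drift.

**Detection.** A dive is a maximal excursion below the 2 m surface
threshold, retained only if it exceeds 32 s in duration and 15 m in
depth. The post-dive interval is the surface time to the next dive.

**Metrics.** The bottom phase spans the first to last sample deeper than
80% of the dive's maximum depth — a common biologging convention,
configurable because published pipelines differ. Dive efficiency is
bottom time over duration. Vertical excursions ("wiggles", the standard
prey-capture-attempt proxy) are counted by pruning the local-extrema
sequence of the bottom trace until every reversal has amplitude of at
least 5 m, then counting the shallow-ward reversals. The 5 m threshold
sits well above the depth-sensor noise floor at 8 s sampling.

**Classification.** Dives are assigned to one of four types by
hierarchical rules, evaluated in order: *drift* if the dive contains a
contiguous monotone segment covering at least 40% of its duration, and
at least 300 s, at a vertical rate no faster than 0.4 m s⁻¹ (rates are
computed on a 40 s running mean so the monotonicity test is robust to
sensor noise); *benthic foraging* if the maximum depth is within 10% of
the local seafloor depth and the bottom fraction is at least 15%;
*pelagic foraging* if the dive has at least one bottom excursion and the
same bottom fraction; otherwise *transit*. The 300 s floor on the drift
segment reflects the biology — passive drifts last minutes — and keeps
degenerate short V-dives from qualifying. The reference classifiers in
this literature are unpublished toolboxes; this hierarchy is our
declared, testable stand-in, and every threshold is exposed in
`classifier_params()`. Benthic-looking dives require a seafloor depth at
the dive's position; dives that cannot be georeferenced (outside the
track's span) skip the benthic test and are flagged.

**Diel assignment** uses the NOAA solar-position approximation at the
dive's midpoint: zenith ≤ 90° is day. A civil-twilight convention (96°)
is available. Dives are georeferenced by linear interpolation of the
hourly track at the dive midpoint.

## Trip-level foraging variables

A position is a *foraging location* iff its transit speed is below
2 km h⁻¹ — the area-restricted-search threshold for this species — and
at least one pelagic- or benthic-foraging dive is georeferenced to that
hour. From the flags we derive: the proportion of time feeding; the mean
distance from foraging locations to the 200 m isobath (the continental
shelf edge); the foraging area as the 95% contour of a 2D kernel
utilization distribution on a 2 km grid (Silverman reference bandwidths,
recorded in the output, standing in for a GIS vendor's unspecified
default); the trip typology (*focused* if fewer than five foraging
locations fall outside the farthest-point segment, the contiguous hours
at ≥ 90% of the trip's maximum colony distance, else *throughout*); the
ecoregion containing at least 50% of foraging locations (else
"multiple"); and a habitat type — *coastal* when at least 90% of
foraging locations lie within 30 km of the shelf edge, *open ocean* when
at most 10% do, *coastal/open ocean* between. The 30 km / 90% / 10%
habitat cuts and the 90% apex definition are package choices where the
literature delegates to references; all sit in `foraging_params()`.
Distance to shelf is averaged over foraging locations only (not all
positions), matching the feeding-centric reading of the variable.

The 31-variable trip summary comprises those three spatial variables,
the four dive-type proportions, and — for pelagic and benthic foraging
dives by day and night — mean maximum depth, duration, bottom time,
post-dive interval, excursion count and efficiency. Cells without dives
are missing and flagged, never silently zero.

## Bioenergetics

Body masses are measured days after arrival ashore; fasting corrections
reconstruct arrival mass. For females, daily mass loss follows
`0.51 + 0.0076 × mass` (kg d⁻¹); the correction iterates this recursion
day by day from the census mass backwards, and post-moult mothers have
their pup's mass added back before correcting. For males, daily energy
expenditure is `multiplier × 293.1 × mass^0.75` kJ d⁻¹ — 2× predicted
basal during the moult, 3.1× during breeding — converted to mass through
a fasting fuel mix of 93% lipid / 7% protein energy and tissue energy
densities of 37.3 kJ g⁻¹ (lipid) and 23.5 kJ g⁻¹ (protein). The Kleiber
coefficient 293.1 and the fuel mix are exposed as parameters since the
sources report them indirectly. Energy gain assumes adipose tissue is
90% lipid and lean tissue 27% protein. Eight foraging-success metrics
follow: departure mass, corrected gain, gain rate over the trip and per
feeding day, proportional gain, energy gain, and energy-gain rates;
feeding days are the feeding proportion times trip days, and relative
rates are undefined (flagged) when no feeding was detected.

The backward recursion makes the correction the exact inverse of the
fasting process it models: simulated cohorts corrupted by onshore loss
are recovered to machine precision, and an explicit forward-Euler
corruption (the opposite discretisation) is still recovered to well
under 1% of a realistic gain.

## Strategy clustering

Deployments missing more than half of the 31 variables are excluded;
remaining gaps are imputed by regularized iterative PCA (rank 3,
singular values shrunk by the estimated noise floor, 100 iterations,
tolerance 10⁻⁶) — the same family of method the missing-data PCA
literature recommends for this design. Variables are centred and scaled;
components with eigenvalue ≥ 1 that explain ≥ 10% of variance are
retained, with a deterministic sign convention. Retained scores feed
Ward hierarchical clustering (Ward.D2 — the criterion with squared
distances; "Ward's method" is ambiguous between hclust's two variants
and we document the choice), with the cluster count chosen by maximum
average silhouette over k = 2…8 (ties to the smaller k) and
within-cluster sums of squares reported for elbow inspection. Silhouette
is primary and the elbow advisory because the two rules need a
tie-break. Per-variable discrimination uses Gaussian identity-link GLMs
against the cluster factor: likelihood-ratio test versus the
intercept-only null, small-sample AICc, Type-II Wald ANOVA, and
Tukey-adjusted pairwise contrasts of estimated marginal means. Diel
day/night comparisons use Shapiro–Wilk to choose between Welch's t and
Mann–Whitney, with Bonferroni correction over each comparison family;
constant vectors force the nonparametric branch.

## Spatial overlap

Utilization distributions are Gaussian product-kernel densities on
regular 2D or 3D lattices, with diagonal bandwidths from the univariate
plug-in selector per dimension (Silverman's rule as fallback, recorded).
Full-matrix plug-in selection is out of scope; the diagonal restriction
is documented in each result. For 3D, each foraging location carries its
maximum dive depth, rescaled to km so bandwidth selection is not
dominated by a unit mismatch. Lattices pad three bandwidths beyond the
data and are shared between groups being compared. A level-p region is
the smallest set of highest-density cells holding p of the mass — 95%
for foraging range, 50% for the core area. Overlap reports each group's
region measure, the intersection measure, percent overlap relative to
each group, and the utilization distribution overlap index: the
intersection measure times the integral of the density product over the
shared lattice, computed over the union support as the estimator's
definition requires. UDOI is 0 for disjoint use, ~1 for complete overlap
of two uniform distributions, and can exceed 1 for concentrated shared
use. Grid convergence (UDOI moves < 1% on lattice refinement), symmetry
and closed-form anchors (offset Gaussians against quadrature, uniform
squares) are all under test.

## Mortality attribution and modelling

A stopped transmitter is attributed in decision order: transmitted to
the trip's end → survived; stopped at sea but the animal resighted in a
later season → tag failure; stopped, never resighted, with location
quality degrading over the final 30 transmitting days (one-sided
Mann–Kendall on the daily best-class rank, p < 0.05) → tag failure;
otherwise → presumed dead. The 30-day window and the 0.05 one-sided test
are declared stand-ins for the qualitative "degraded quality over time";
records shorter than the window use what is available and are flagged.
Tag-failure animals never resighted are coded as survivors in the
mortality models, the coding that reconciles a per-sex death probability
with the per-sex death counts.

Death risk is modelled by binomial logit GLMs over all subsets of
{sex, trip, year} that contain sex, year as a factor; "individual"
cannot enter with one observation per deployment and is excluded. Models
are ranked by AIC with a ΔAIC ≤ 7 shortlist; the best model receives a
likelihood-ratio test against the null, a Hosmer–Lemeshow test (10
groups), and a Type-II Wald ANOVA. Marginal death probabilities per sex
average predictions over the other terms' levels on the link scale with
back-transformed Wald intervals; on a sex-only model they reduce exactly
to the group death fractions. Last-location metrics (position, transit
rate in m s⁻¹, shelf distance, ecoregion, trip portion —
outward/farthest point/return by the same 90% apex rule) feed
Mann–Whitney comparisons between dead males and dead females with
Bonferroni correction.

## The synthetic cohort generator

The generator's defaults encode the study conditions for this species:
three strategies — males (~126-day biannual trips to the continental
shelf, benthic-dominated diving), post-breeding females (~76 days,
pelagic, a few hundred km beyond the shelf) and post-moult females
(~220 days, pelagic, ranging farther, feeding throughout) — with a
two-state movement model (transit at ~4 km h⁻¹ with persistent headings;
area-restricted search at ~0.7 km h⁻¹, safely under the 2 km h⁻¹ rule),
ARGOS sampling at ~1.2 fixes h⁻¹ with class-dependent error and a 2%
outlier rate, and four dive archetypes: two-slope V transit dives
parameterized by vertical rate, trapezoidal foraging dives with
sinusoidal bottom wiggles (pelagic dives 80 m shallower at night,
tracking diel prey migration; benthic dives at 98.5% of seafloor depth),
and drift dives with a slow monotone segment. Archetypes are
habitat-conditional: benthic foraging requires a seafloor within 600 m,
pelagic foraging requires mid-water clearance above the seafloor
(maximum depth 0.7 × seafloor − 130 m, at least 100 m), as the animals
themselves behave; a drawn archetype the habitat cannot support becomes
the one it can. The seafloor under a dive is evaluated at the dive's
interpolated midpoint position — the same georeferencing the analysis
applies — so that ground truth and analysis refer to the same quantity.
Depth noise is 1 m Gaussian by default with optional surface drift to
exercise the zero-offset correction.

Geometry is deliberately analytic: a straight 200 m isobath 60 km
offshore of the colony, a piecewise-linear seafloor (shoaling shelf,
45 m km⁻¹ slope, 3900 m abyss) and three rectangular ecoregions in the
colony-centred plane, so that every distance and containment is
checkable by hand. Body records draw departure masses and gains at the
three strategies' reported scales with adipose fractions chosen to
reproduce the corresponding energy gains, then apply the fasting models
forward so the correction can be validated by inversion. Tag fates are
drawn per sex (death 17/39 and 22/178; failure 8/39 and 24/178);
failures degrade monotonically over their final month while deaths stop
with a trend-free class pattern. Fate evidence always lives on the
nominal trip timeline, so attribution behaves identically when movement
is scaled down. A fixed, RNG-free 217-deployment fixture
(`make_cohort_fixture()`) encodes the cohort accounting — 39 males
with 25 stopped tags (8 failures + 17 deaths) and 178 females with 46
stopped (24 + 22) — deterministically, with the death pattern built so
the Mann–Kendall test is comfortably non-significant (p ≈ 0.17).

**What the generator does not emulate.** No ocean currents, prey fields
or environmental covariates; no haul-outs mid-trip; dive shapes are
stylized (the transit V carries a brief steep terminal spike so its
bottom phase stays under 10% of duration at 8 s sampling; real descent
rates vary smoothly); ARGOS error is isotropic Gaussian rather than the
heavy-tailed, anisotropic reality; the seafloor is one-dimensional.
Consequently, passing recovery tests demonstrates internal consistency
of the chain — detection, classification, georeferencing, correction and
clustering recover what was planted — not field validity of any
threshold. Thresholds retain their literature values precisely so that
the package applied to real data behaves as the published pipelines do.

## Problem sizes and numerical choices

The test suite and the acceptance script run cohorts scaled for a
single-CPU desk machine: `trip_scale` shortens trips (about 1.5–2.6 days
for recovery suites) while leaving all per-hour behaviour unchanged, and
the clustering recovery uses 24 deployments on 5-day trips with three
generously separated planted strategies. Monte-Carlo checks use 400–1000
replicates (logistic interval coverage), n = 1000 per sex (fate
frequencies), and lattice steps of 0.04–0.5 km (overlap oracles). The
CTCRW likelihood is optimised with L-BFGS-B on log(β), log(σ) within
[10⁻³, 50] h⁻¹ and [10⁻⁴, 500] km h⁻³ᐟ²; the Kalman filter guards
against non-positive-definite innovation covariances and returns −∞,
which the optimiser treats as a rejected step. Iterative PCA imputation
is regularized by noise-floor shrinkage of singular values. Silhouette
ties break to the smaller k; duplicated points cluster identically.
Degenerate inputs are defined behaviour throughout: all-surface depth
records yield zero dives; fewer than ten foraging locations yield a
flagged, undefined foraging area; single-outcome cohorts refuse the
mortality fit; constant diel vectors take the nonparametric branch.

## Known limitations

The benthic/pelagic boundary is intrinsically ambiguous for
near-seafloor mid-water dives; the classifier resolves it by the 10%
seafloor-proximity rule, and off-shelf "benthic-looking" dives beyond
600 m will classify as pelagic. The smoother assumes a single behaviour
regime per deployment (one β, σ); it does not segment behaviour, by
design. The 2D foraging-area estimate depends on the bandwidth rule
where the original GIS default is unspecified; results record the rule
used. Mortality attribution inherits the one-sided 0.05 Mann–Kendall
convention: about 5% of genuinely trend-free (dead) tags will show a
spurious degradation and be coded as failures, a conservative bias that
the fixed fixture avoids by construction and that users of the
stochastic generator should expect.
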