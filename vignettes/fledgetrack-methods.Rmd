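---
title: "Methods: behaviour labelling, ARS and at-sea associations in fledgetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behaviour labelling, ARS and at-sea associations in fledgetrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fledgetrack analyses GPS tracks of central-place foraging seabirds — birds
that leave a colony, forage at sea and return to the same site. The pipeline
answers four questions about a tracked colony: how do trips look (duration,
distance, range, timing); what was the bird doing at each fix (behavioural
state); where did it search intensively (area-restricted search, ARS); and
which birds moved together at sea (dyadic associations), in particular
whether co-movement coincides with ARS behaviour more often than chance.

## Units and geometry

Coordinates are signed decimal degrees (WGS84), timestamps UTC, internal
distances metres, speeds km/h and angles radians. Distances are great-circle
on a sphere of radius 6,371 km; every proximity threshold in this analysis
(a 500-m colony radius, a 50-m nest exclusion, a 0.002-degree association
box) is far coarser than the sphere/ellipsoid difference. Local clock times
(departure and return) use a configurable UTC offset, default +3 for the
study region.

## Cleaning and trip delimitation

Raw fixes are cleaned by an implied-speed filter: a forward pass drops any
fix whose speed from the last retained fix exceeds 90 km/h. This is a
removal rule, not a cap — capping would fabricate positions. Tracks are then
linearly interpolated onto a regular grid (default 120 s, the coarser of the
two deployment intervals) anchored at the first fix, never extrapolating.

The source analysis does not state how continuous multi-day logs were cut
into trips; we delimit a trip as a maximal run of fixes farther than a
configurable colony radius (default 500 m) from the colony point, extended
by one boundary fix on each side. The radius is deliberately separate from
and larger than the 50-m nest exclusion used for associations. Trips that
touch the start or end of a log are flagged incomplete, and trips outside a
configurable duration window (default 0-24 h) are flagged as outliers;
nothing is deleted, downstream summaries simply skip flagged trips.

## Behaviour labelling

Each fix on the regular grid carries two step metrics: the speed of the
displacement arriving at it, and the absolute turning angle between the two
most recent displacement bearings, folded to $[0, \pi]$. Both quantities
describe the same movement step, so they are undefined for the first two
fixes of a trip; a zero-length displacement keeps the previous bearing, so
stationary stretches read as slow and straight. We evaluate the turn at the
later fix of its two displacements (rather than centring it) precisely so
that speed and turn at a fix refer to one step — this is what makes exact
ground-truth recovery on synthetic tracks a meaningful test.

Labels come from four boxes in the (speed, turn) plane: resting (slow,
straight), intensive foraging (slow, sinuous), travelling (fast, straight)
and relocating (fast, sinuous), delimited at 6 and 14 km/h and 0.30 and
0.43 rad. All intervals are half-open `[low, high)`, giving a total,
deterministic partition. The two published boxes overlap on
$v \in [6, 14) \times \theta \in [0.30, 0.43)$; the original
likelihood-based assignment cannot be reconstructed from its published
description, so that rectangle is resolved by comparing the turn against the
midpoint of the two turn delimiters (configurable). This tie-break is an
explicit deviation, and the package treats the printed delimiters as the
canonical labeller.

An optional unsupervised fitter (`fit_delimiters()`) estimates the four
delimiters from data: a 4-component diagonal-Gaussian mixture on (speed,
turn) fitted by EM, components initialised at the printed box centres, with
delimiters read off pairwise component-density intersections per variable
conditional on the other variable's regime. It is a simplified stand-in for
full binary-clustering labellers: no per-point uncertainty weighting, no
label smoothing. It defaults off.

## ARS zones

An ARS zone begins as a run of at least 3 consecutive intensive-foraging
fixes. Runs separated by fewer than 4 fixes of *other* behaviour are merged
transitively; sub-threshold foraging runs are discarded before merging and
do not count toward gap size (they are not "another behaviour"), nor can a
gap resurrect them. Each merged zone is summarised by the coordinate-wise
median of its member fixes (centroid), its time span, its great-circle
distance from the colony, and a surface. The surface method behind the
published per-zone areas is unstated; we use the convex hull of the member
fixes in a local equirectangular metre projection because it is
deterministic and parameter-free, and document it as a guess. Collinear or
coincident members give surface 0.

Because the 3-fix minimum is keyed to the sampling grid, the zone count is
resolution-sensitive: regridding 1-min tracks to 2 min merges short bouts
below the threshold and roughly halves zone counts in our synthetic
colonies. The tests therefore check order-of-magnitude stability across
grids, not exact invariance.

Utilisation areas use a bivariate normal kernel on the member fixes (or,
configurably, zone centroids) projected to a local metric plane: reference
bandwidth $h = \sigma n^{-1/6}$ per axis with $\sigma$ the mean of the two
axis standard deviations, density evaluated on a 256 by 256 grid covering
the data plus three bandwidths, and the area at an isopleth counted as the
cells of the smallest density region holding that share of total mass. On a
large bivariate normal sample the 95%/50% area ratio reproduces the
closed-form $\ln 0.05 / \ln 0.5$ within grid error, which the tests assert.
Exact translation invariance holds along a parallel; a latitude shift
perturbs only the $\cos(\mathrm{lat})$ scaling of the projection.

## Associations

Two fixes of different birds form an association event when both the
latitude and longitude differences are *strictly* below 0.002 degrees and
the fixes are *at most* 30 s apart — strict degree thresholds and an
inclusive time threshold, following the published wording literally.
Detection runs on the raw (speed-filtered, non-interpolated) tracks: on a
2-min grid a 30-s window would only match simultaneous grid points.
The join is a sorted time-window merge, never a full temporal cross
product, and the tests pin it to a brute-force all-pairs oracle.

Events with either member within 50 m of the nest are discarded (the
published rule does not say which member; we drop the event if either is
close), and unordered bird pairs contributing exactly one event are ignored
as chance encounters. "Simultaneously associated" group sizes are
operationalised by binning events on the clock (default 60 s) and taking
connected components of the bird-pair graph within each bin, so
co-membership is transitive through shared partners.

## The independence statistic

If a fraction $f$ of all locations is in ARS behaviour and association is
independent of behaviour, an associated fix pair contains no ARS member
with probability $(1-f)^2$, two with probability $f^2$, and exactly one
with the complement. Observed (0, 1, 2)-member counts are tested against
this expectation with a Pearson goodness-of-fit statistic on 2 degrees of
freedom, no continuity correction. The pipeline recomputes $f$ from its own
labels (the share of labelled fixes inside merged ARS zones) rather than
taking it as given; the analytic construction itself is exposed separately
and accepts any $f \in (0,1)$. Pairwise proportion comparisons use the
Marascuilo procedure with the $\chi^2_{k-1}$ critical range; the source
gives no simultaneous level, so the default is $\alpha = 0.05$.

A calibration generator draws pair states as a mixture: with probability
$\rho$ the two members share one Bernoulli($f$) draw, otherwise they are
independent, which inflates both same-state cells by $\rho f(1-f)$.
$\rho = 0$ is the exact null — the test's type-I rate at $\alpha = 0.05$
sits in $[0.035, 0.065]$ over 1,000 simulations of 2,000 pairs — and
$\rho = 0.2$ is the default planted effect, at which rejection is
essentially certain at that sample size.

## The synthetic colony

The simulator is first-class, tested code: it defines the study conditions
under which the pipeline is validated. Movement is a discrete-time
correlated random walk in a local flat approximation (1 degree latitude =
111.32 km, longitude scaled by $\cos(\mathrm{lat})$), adequate within the
~100-km ranges simulated. At each step a behavioural state is drawn from a
4-state Markov chain, speed and absolute turn from per-state truncated
normals, and the heading rotates by the turn with a free sign. Since the
analysis folds turns to $[0, \pi]$, the sign carries no behavioural
information, and the simulator uses it for steering — along per-bird
azimuthal corridors in separable mode, and homeward on the return leg —
without ever breaking the (speed, turn) ground truth attached to each fix.

Defaults emulate the study conditions: a colony at 22.3 S, 40.3 E; 60-s
(juvenile) and 120-s (adult) sampling; one trip per day (two on a small
fraction of days, 3.6% juvenile / 5.5% adult); departures mid-morning
(juveniles around 11:00 local, adults around 09:00); trip durations drawn
from truncated normals at 4.8 +/- 2.6 h (juveniles) and 9.1 +/- 4.0 h
(adults), bounded to 0.3-14.9 h; foraging ranges around 15 km (juveniles)
and 60 km (adults). A trip is an outbound travelling commute to a drawn
range, a Markov foraging phase, and a timed return leg: the bird turns home
when the estimated time to reach the colony (range over cruise speed plus a
turn-around allowance) meets the scheduled duration. This closure rule
guarantees closed trips and the central-place inequality
(distance $\ge$ 2 range $-$ 2 colony radius) but makes realised durations
approximate — scheduling error is a few fixes, not one, which is why the
duration-recovery test uses a 15% band rather than one step.

In separable mode the per-state distributions sit strictly inside one class
box each and outside the ambiguous rectangle, so the box labeller must
recover the planted states exactly; bird corridors keep non-associated
birds well beyond 0.003 degrees of each other at sea, so detector precision
against planted truth is exact too. Realistic mode lets distributions
overlap the boundaries, and the labeller is required only to exceed 90%
recovery. Planted co-movement replaces a follower's positions over the
leader's at-sea window with the leader's positions plus independent uniform
jitter below 0.001 degrees per axis; the follower has no movement-model
truth there, so its true states over the window (plus the two contaminated
fixes each side) are recorded as NA and excluded from accuracy scoring.
Ground-truth associations are stored as per-pair windows and expanded to
per-fix pairs for recall/precision scoring.

What the simulator does not emulate: wind and bathymetry forcing, nest
attendance and provisioning, device failure and irregular sampling, and
spatially structured prey fields. Passing tests therefore demonstrate that
the pipeline's rules are implemented exactly and recover a known generative
process — not that the printed field-data values (which require the
unreleased tracking data) are reproduced.

## Problem sizes and determinism

The validation colony is 10 birds (6 juveniles, 4 adults) over 5 days —
about 58,000 fixes — with three planted episodes including one three-bird
group; chain-level checks use 20,000-40,000-step free walks with
batch-means standard errors (the chain is autocorrelated, so i.i.d. errors
would be too tight); the statistic calibration uses 1,000 replicates of
2,000 pairs; kernel checks use 10,000-point Gaussian samples. Every source
of randomness flows from a single configured seed, and an identical seed
reproduces the entire report bundle bit for bit.

## Known limitations

* The ambiguous-rectangle tie-break is a documented guess at an
  unpublishable detail; delimiters and tie-break are configurable.
* ARS zone counts and surfaces are grid- and hull-convention dependent.
* The kernel grid (256 per axis) discretises isopleth areas; at very small
  point counts the reference bandwidth over-smooths.
* Group sizes depend on the binning width; 60 s matches the finest sampling
  interval but is a modelling choice, not a published rule.
* Trips crossing midnight are handled, but multi-day excursions are only
  flagged, not segmented further.
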