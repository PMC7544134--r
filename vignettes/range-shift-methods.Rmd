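---
title: "Methods: from presence-only records to range-shift metrics and priority maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from presence-only records to range-shift metrics and priority maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avishift)
```

avishift chains the standard steps of a national-scale, presence-only
assessment of climate-driven bird range shifts into one tested pipeline:
occurrence cleaning, collinearity screening, presence-background niche
modelling with replicated cross-validation, threshold binarization into
range maps, displacement and richness analytics, and weighted core-area
zonation prioritization with a protected-area gap analysis. Every stage is
exercised end to end on seeded synthetic worlds whose generating process —
and therefore whose correct answer — is known exactly.

This vignette documents the models, the parameters that matter, the
numerical conventions, and the design decisions taken where published
practice leaves the details open.

## The synthetic world

Real inputs of this kind are occurrence archives from birdwatching,
30-arc-second bioclimatic rasters, a digital elevation model, province
polygons and reserve masks. The generator emulates their structure at desk
scale:

* **Climate.** Each band is a deterministic gradient plus seeded white noise
  smoothed by a box kernel (`smoothing_scale` half-width, default 4 cells) —
  the cheapest spatially autocorrelated field with controllable structure.
  Band 1 (`temp`) falls poleward, spanning about 10 units across the grid;
  later bands carry weaker east–west (coastal/continental) gradients of
  alternating sign, so inter-band correlations are moderate rather than
  degenerate, as in real bioclim stacks. The future scenario is the current
  field plus a per-band additive offset, so the imposed displacement is
  known exactly.
* **Resolution.** Default 0.1° on a 60 × 80 grid (6° × 8°), not 30
  arc-seconds: full runs take seconds while every algorithm sees realistic
  spatial structure.
* **Terrain.** Elevation rises quadratically toward the west (up to
  ~5,200 m) plus smoothed relief, covering most of the 0–500 m … 5,000 m+
  diversity bands.
* **Regions and reserves.** Regions are axis-aligned contiguous blocks
  (trivially contiguous province analogues, enough to exercise
  region-restricted background selection). The reserve mask takes the upper
  tail of a smoothed noise field, giving clumped patches at a configured
  cover fraction (default 15%).
* **Species.** Each virtual species has a Gaussian niche
  $s(\mathbf{x}) = \exp\!\big(-\tfrac12 \sum_v ((x_v - \mu_v)/\sigma_v)^2\big)$
  in the temperature band (optima drawn from the interior 15–85% of its
  distribution, breadths 0.8–1.6 units); half the pool also responds to a
  second climate band. Occurrences are multinomial draws over cells with
  probability proportional to suitability times an optional effort surface
  (a smoothed log-normal field), then jittered uniformly within the cell.
  Effort bias is on by default because geographic reporting bias is a
  defining feature of citizen-science archives; tests can toggle it off.
* **Default cohort.** 20 species with 300 points each — comparable, per
  species, to the locality counts typical of national birdwatching archives
  — under two future scenarios warming the temperature band by +1 and +3
  units (low- and high-emission analogues).

What the generator does **not** emulate: realistic climate fields and their
cross-correlations, dispersal limitation, demographic lags, temporal
turnover in recording effort, and coastline/border geometry. Passing tests
therefore demonstrate that the algorithms recover known structure under
controlled violations (sampling bias, collinearity), not that any real
fauna behaves this way.

## Occurrence cleaning

Records are validated against the study bounding box, exact duplicate
localities are collapsed, and species with fewer than five independent
localities are excluded (`min_localities = 5`). Whether deduplication
precedes the five-locality count is an open detail in common practice; here
duplicates are removed first, on the reading that "independent localities"
implies distinctness.

Presence thinning enforces a minimum separation of one arc-minute between
conspecific records, measured as Euclidean distance in degree space (the
unit in which the criterion is stated; ≈1.8 km east–west at 30° N). Points
are visited in seeded random order and kept iff no already-kept conspecific
neighbour lies within the separation — randomized removal, reproducible
under the seed, O(n·k) with a grid-bucket index. After thinning the
five-locality rule is re-applied, since thinning can push a species below
it.

Spatial-uniformity diagnostics summarize sampling bias: mean center,
geometric-median center, their great-circle offset, the standard distance
(RMS great-circle distance from the mean center), and the share of points
inside the standard-distance circle.

## Variable screening

Pearson correlations between all climate-band pairs are computed at the
pooled presence sites. Iteratively, the variable involved in the most
high-correlation pairs (|r| > 0.9) is removed until no pair exceeds the
threshold. The iteration and tie rules are not fixed by common practice, so
they are fixed here: ties on pair count break by the largest mean |r|
against all remaining variables, then lexicographically — deterministic and
defensible. Constant variables are removed first with a warning. Elevation
joins the model after screening, alongside the retained climate bands.

## The niche model

The presence-background model is a ridge-penalized log-linear
(logistic-form) fit of presences against background cells on standardized
linear + quadratic terms per variable, reported through the cloglog link

$$p = 1 - \exp(-\exp(\eta)), \qquad
\eta = \beta_0 + \sum_v \beta_{v,1} z_v + \beta_{v,2} z_v^2 .$$

Linear + quadratic features represent a Gaussian niche exactly, keep the
fit convex, and avoid the variance of hinge/threshold features — a
deliberate simplification relative to full maximum-entropy feature sets.
The penalty (default strength 1 on standardized features, intercept
unpenalized) is solved by Newton/IRLS to a coefficient tolerance of 1e-10;
an independent penalized solver (glmnet) confirms the optimum in the test
suite. Standardization constants come from the pooled presences +
background of the fit.

Presences are split into five seeded folds; each replicate trains on 80%
plus the shared background and is scored by rank-based AUC on the held-out
20%. The suitability surface reported for range mapping is the **mean of
the per-replicate cloglog surfaces** (the averaged replicate output); the
all-data fit is stored for coefficient pruning and inspection. Variables
that are constant over the training data are dropped with a warning; a
model with every variable constant degenerates to an intercept-only fit
with uniform suitability.

Background defaults to 10,000 cells (standard presence-background
convention), capped by the number of eligible cells — on the default
synthetic world the cap binds and background is effectively exhaustive.

## Two rounds, thresholds, and range maps

Round one fits every species on all screened variables + elevation against
an unrestricted background. Two filters follow:

* **Locality density.** The predicted range is tiled into 3° × 3° blocks;
  a species is excluded iff localities per intersected block are strictly
  below 1 (density exactly 1 is retained).
* **Zero contribution.** Variables whose absolute standardized coefficient
  mass |β₁| + |β₂| is ≤ 1e-8 in the all-data fit are dropped per species.
  (A percent-contribution decomposition of the fitted model is not uniquely
  reconstructible; coefficient mass is this package's operational
  definition.)

Round two refits survivors with their own variable sets and a
region-restricted background (cells drawn only from regions holding at
least one presence — the background-selection bias correction), then
projects suitability for the current and every future scenario.

The binarization threshold per species is the maximum of test sensitivity
plus specificity (MTSS). Candidate thresholds are the midpoints between
adjacent distinct pooled scores plus the extremes; ties return the smallest
maximizer. Scores are pooled held-out presences across the five replicates
against the shared background scored by the replicate mean — pooling is not
fixed by convention, so it is fixed here and tested against brute-force
enumeration. Binarization uses ≥ (presence at exactly the threshold);
because candidates are midpoints the choice rarely binds, but it must be
deterministic.

## Range dynamics

* **Areas** are reported as presence-cell counts and km² (spherical
  cosine-latitude cell area, R = 6371 km); percentage change uses cell
  counts, since no area basis is canonical.
* **Median centers** are geometric medians (Weiszfeld iterative
  reweighting, tolerance 1e-8 degrees, distances in a local
  equirectangular frame about the centroid, with a small-distance guard
  against coincidence with a data point). The objective is planar, as in
  standard GIS "median center" tools, while reported displacement distances
  use the haversine formula.
* **Displacement vectors** carry great-circle distance, initial bearing
  from north, and a compass quadrant from the signs of (Δlon, Δlat); north
  requires strictly positive Δlat, so zero-component shifts classify
  south/west and are flagged. Identical centers give a zero vector with an
  undefined, logged quadrant.
* **Richness** is the per-cell sum of range maps; the double-counting
  identity (Σ cells of richness = Σ species of area) is asserted on every
  run.
* **Elevation-band diversity** counts species with ≥1 presence cell per
  half-open band (0–500, 500–1,000, …, 4,000–5,000, 5,000+ m; membership
  at an edge goes to the upper band). "Diversity" is a species count, not
  summed richness, matching the usual reading of per-band species
  diversity. The **turning point** is the lowest band edge with
  non-positive diversity change in every band entirely below it,
  non-negative change in every band at or above it, and at least one strict
  loss below and strict gain above — the strictness clause makes an
  unchanged profile return "none" rather than a vacuous edge. This
  detection rule is the package's own; published turning-point figures come
  from real data and do not pin down a rule.

## Prioritization

Species weights must be positive, decreasing in range change (losers get
high weight), and carry a +0.5 endemic bonus. A raw percentage change does
not satisfy these properties simultaneously (it is negative for losers),
so the package adopts

$$w = \operatorname{clamp}(1 - \Delta/100,\; 0.1,\; 2.0) + 0.5\,[\text{endemic}]$$

which preserves every stated qualitative property while staying bounded: a
species losing half its range gets 1.5, a stable species 1.0, strong
expanders floor at 0.1.

Cell ranking follows basic core-area zonation: the marginal loss of cell
$i$ is $\max_j w_j\, p_{ij} / Q_j$, with $Q_j$ species $j$'s suitability
summed over not-yet-removed cells; each iteration removes the
`warp_factor` cells with smallest marginal loss without intra-batch
recomputation (warp semantics; default 1,000 at pipeline scale, 1 in
oracle-comparable tests). Ties break by marginal loss then row-major cell
index. Rank = removal position / land cells, so the best cell ranks 1.
With a reserve mask the masked-in cells are removed first in their own
greedy phase — "priorities outside reserves" — so every top-fraction cell
lies outside the mask; whether to exclude or rank-first reserve cells is
genuinely open, and removal-first is adopted (and configurable) because it
keeps the full ranking defined. The warp-1 algorithm is verified exactly
against a brute-force greedy oracle.

Top-30% and top-50% fractions and their reserve coverage (share of
selected cells inside the mask) provide the gap statistics.

## Reproducibility and numerical conventions

* One master seed; every stage derives its own stream by hashing the stage
  label into the seed, so a stage can be re-run in isolation.
* Rasters are north-up, cell-center registered, WGS84 lon/lat; a point
  belongs to the half-open cell [edge, edge + Δ). File exchange uses ESRI
  ASCII grids (single band per file; multiband as per-band files plus a
  JSON manifest), which round-trip values, missing mask and georeference
  losslessly in plain text.
* CSV outputs are UTF-8, comma-separated, "." decimal; manifests record
  seeds, per-stage counts, exclusion logs and MD5 checksums, so two runs of
  the same configuration are byte-identical — asserted in the tests.
* Test problem sizes: unit fixtures are ≤ 100 cells; end-to-end runs use a
  40 × 48 world with 10 species × 200 points; recovery checks use the full
  60 × 80 default with 20 species × 500 points. These sizes are chosen so
  the whole suite completes in well under a minute while leaving every
  algorithm non-trivially exercised.

## Known limitations

* Linear + quadratic features cannot represent skewed or bimodal niches;
  the fitted optimum is the stationary point of a parabola.
* The cloglog surface is a monotone transform of the linear predictor, so
  AUC is unaffected by the link, but absolute suitabilities depend on the
  background-to-presence ratio.
* The greedy zonation ranking is exact for its own rule but, like all
  greedy reserve selection, not globally optimal; no connectivity or
  boundary-length terms are included.
* Group comparisons are descriptive (counts and means); between-group
  hypothesis testing is out of scope.
* Turning-point detection requires a clean sign change across bands;
  profiles with non-monotone change patterns legitimately return "none".
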