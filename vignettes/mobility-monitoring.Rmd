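---
title: "Monitoring urban mobility from geotagged point streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring urban mobility from geotagged point streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobflow)
```

## The monitoring problem

Geo-located social-media posts are one of the few openly collectable,
continuously updated traces of where people actually spend time in a
city. `mobflow` turns a raw stream of `(user, timestamp, lat, lon)`
records into interpretable mobility measurements at two scales: global
daily indices that track how actively and how far people move, and
weekly zone-level flow networks that track *where* activity concentrates
— and it relates the latter to weekly zone-level disease-case counts
with spatial correlation statistics. The intended use is epidemic-period
monitoring: quantifying a lockdown's mobility shock, watching recovery,
and testing whether visit patterns align spatially with case counts.

The package assumes nothing about the platform beyond the four record
fields. All geography is WGS84; zone systems are polygon collections
with unique ids (census-style reporting zones in real applications, grid
tessellations in the bundled generator — the statistics downstream
depend only on contiguity topology and flows, which is why a grid is an
acceptable stand-in).

## Cleaning

Three filters run in a fixed order, each reported in a
`cleaning_report`:

1. **Study-area crop** — point-in-polygon against the zone system;
   boundary points count as inside (a determinism choice: every point on
   a shared edge has exactly one well-defined zone, the first in id
   order).
2. **Abnormal accounts** — users whose total post count in a calendar
   year exceeds `mean + k_sd * SD` (sample SD, strict inequality, k_sd
   default 1) of that year's per-user counts are removed entirely. These
   are overwhelmingly bots and commercial accounts. SD over a single
   user is undefined and treated as "keep". Note this rule is a
   *single-pass* definition: removing the tail shifts the threshold, so
   re-applying it can remove more users. The pipeline applies it once,
   and its tests assert idempotence only for the two filters that
   guarantee it (crop and static).
3. **Static users** — users whose every point repeats one exact
   coordinate pair can never generate a trip and are dropped. Inexact
   near-duplicates are left to place detection, which collapses them
   into a single place (and hence zero trips) anyway.

With `k_sd = 1` the account filter is aggressive — it trims roughly the
top sixth of a near-symmetric count distribution — and, because movers
post more points than non-movers, it biases the recovered moving-user
rate slightly downward. That is a property of the rule itself, visible
in the README's worked example; sensitivity analyses can raise `k_sd` or
disable the filter with `Inf`.

## Places, trips and the two indices

A *place* is a cluster of one user's points under DBSCAN with haversine
distances, `min_pts = 1` and `radius_m = 500` (meters; a conventional
walkable distance — the intent is to absorb coordinate jitter around a
venue, not to segment neighbourhoods). With `min_pts = 1` DBSCAN is
exactly the connected components of the graph linking point pairs within
the radius; the implementation is tested against a brute-force component
search, and supports `min_pts > 1` (core/border/noise) for users with
denser streams.

Two scope decisions are deliberately explicit because they are easy to
get wrong:

- **Clustering scope is per user-day** (configurable to per-user).
  A single global clustering at 500 m over a dense city would chain the
  whole centre into one place by transitivity; jitter is a property of
  one user's posts around one venue.
- **"Within 24 hours" means one local civil day** (default
  `Europe/London`), because the indices are daily and aggregate by
  calendar date. Displacements crossing local midnight are not trips.
  All timestamps are stored as UTC instants and converted for day
  assignment, so daylight-saving transitions are handled correctly.

Within a user-day, points are ordered chronologically and every
consecutive pair assigned to different places emits one trip (origin the
earlier place, destination the later, distance the haversine between
centroids on a 6,371,000 m sphere). Trips are consecutive-pair
displacements — not all place pairs — so trip counts are additive over
the day's sequence.

For day *t*, `m_rate` is the fraction of the day's active users who made
at least one trip, and `avg_dis` is the mean over movers of each mover's
mean trip distance. The second average is user-weighted by construction:
a courier with forty trips counts once, like everyone else. Annual or
period summaries report the headline ratio under both conventions —
ratio of daily means and mean of daily ratios — because they differ
whenever activity varies across days; the ratio-of-means convention is
the primary one in `summarize_indices()`.

`decompose_series()` is classical additive moving-average decomposition
(period 7 by default): the trend is the centered period-length moving
average, the seasonal component is the per-weekday mean of the detrended
series re-centered to sum to zero, and the residual is the remainder.
On a noiseless linear trend plus a fixed weekly pattern it recovers both
exactly (a test asserts this to 1e-9), which is the right sanity bar for
an algorithm this simple.

## Weekly flow networks

Trips whose endpoint centroids both fall inside the zone system are
assigned by point-in-polygon (failures are dropped and counted) and
aggregated into Monday-start weekly origin-destination matrices;
intra-zone trips are kept as self-loops. Weeks are dated by trip date.
The three epidemic analysis windows (first wave, summer relaxation,
second wave) and their year-earlier baseline windows are configured as
named date ranges in `pipeline_config()`; period aggregation is the sum
of the member weekly matrices, and a test asserts trip conservation
through every aggregation step.

**Attractiveness** `A(i,t)` is the weighted degree of zone *i* divided
by the period's total trip count. The denominator is *total trips* —
not the zone's own out-flow — which makes `A` a share over zones that
sums to one and makes the period-to-period difference zero-sum, so
"which zones gained at whose expense" is directly readable. The default
direction is `"in"` (arrivals: attractiveness as visits drawn), with
`"out"` and `"total"` available since degree direction is a modelling
choice, not a fact.

**Communities.** Modularity-based community detection runs on the
symmetrized graph (flows summed over directions; modularity for directed
graphs has no single accepted definition) with the deterministic greedy
agglomerative algorithm; vertices are entered in sorted zone-id order so
reruns and input orderings cannot change the result. Self-loops are
excluded from the merge heuristic but included in the reported Q, which
a test recomputes independently from the returned labels and also
verifies against exhaustive search over all partitions of an 8-node
two-clique network. Communities smaller than `mean size − 1 SD`
(floored at 1) are flagged *isolated* — areas weakly connected to the
rest of the city. The threshold is a package choice where several
readings were defensible; it is configurable, and SD = 0 (all sizes
equal) flags nothing.

**Profiles.** Each zone's attractiveness over the analysis week index
(112 weeks in a full two-year study window) forms a fixed-length vector,
zeros for silent weeks. Zones are clustered by agglomerative
hierarchical clustering under correlation distance `d = 1 − r` with
average linkage — correlation rather than Euclidean distance because the
object of interest is the shape of the temporal trend, not its level;
average linkage because it is the robust default for correlation
distances (complete and single are available). Zero-variance profiles
have no defined correlation and are dropped with a report. `k = 3` is
the default cluster count; selection remains a judgement call supported
by the exposed dendrogram, not an automated criterion. Rows are
processed in sorted zone-id order, making merge order deterministic.

## Spatial statistics

Queen contiguity (zones sharing at least one boundary point) is detected
through shared polygon vertices with coordinates rounded to 1e-9
degrees. For grid tessellations — and any zone system whose shared
boundary points are vertices of both polygons — this is exact; for
polygons that touch only along the interior of an edge it would miss the
pair, a documented limitation of the vertex-hash approach. Weights are
row-standardized; islands get zero rows and are reported.

With centered values `z_i = x_i − x̄`:

- global `I = (n/S0) Σ_ij w_ij z_i z_j / Σ_i z_i²`,
- local `I_i = ẑ_i Σ_j w_ij ẑ_j` with population-SD standardized `ẑ`,
- bivariate `I_xy = (n/S0) Σ_ij w_ij ẑx_i ẑy_j / Σ_i ẑx_i²`
  (equivalent, under population-SD standardization, to the
  n-denominator form).

All three are tested against naive double-loop oracles to 1e-12.
Inference is by permutation throughout (999 permutations by default; the
weekly suite uses 199 per statistic because it runs four statistics per
week): two-sided pseudo p-values `(1 + #as-extreme)/(n_perm + 1)`,
extremeness measured from the null expectation `−1/(n−1)` for the global
statistic and from the permutation mean for local statistics. The
bivariate null permutes `y` holding `x` fixed (the conventional
conditional scheme); local statistics use conditional permutation
(the zone's own value held fixed, neighbour values drawn from the
remaining zones). Constant inputs are an explicit error for the
statistics, but the weekly suite converts a degenerate week into NA
markers rather than failing, because constant case weeks genuinely occur
in sparse data. Zones with zero attractiveness are real "no visits"
observations and enter as zeros; zones missing from a week's case table
are excluded for that week with re-standardized weights, and logged.

Calibration is part of the test suite: under exchangeable nulls the
rejection rate at α = 0.05 stays within binomial tolerance of α over 50
replicates, and the bivariate statistic is monotone in a planted
attractiveness–case coupling. One subtlety the tests encode: bivariate
Moran's I can only see a coupling through a *spatially structured*
mobility surface — if attractiveness is spatially white, pointwise
coupling moves Pearson's r but not the spatial cross-correlation — so
the coupling fixtures use a smooth centre-weighted surface, which is
also what real cities look like.

## The synthetic-data generator

The generator emulates the features of a real epidemic-period stream
that the pipeline's correctness depends on, with full ground truth:

- **Zone systems**: axis-aligned grid tessellations (default 8×8 cells
  of 0.02°, roughly MSOA-sized at London's latitude).
- **Users and places**: each user has a home activity place, zone chosen
  by a centre-weighted (or uniform) spatial intensity, position uniform
  within the zone.
- **Trips**: on a mover day (probability `p_mover`, default 0.3, which
  can vary by day to emulate a lockdown step), the user performs
  `1 + Poisson(0.3)` trips; distances are log-normal with median 5.4 km
  (`sdlog` 0.8) — a realistic intra-urban daily travel scale; the
  distribution family is a calibration convenience, not a claim. Draws
  are resampled until they exceed
  `radius_m + 2 * jitter_m`: two places jittered toward each other can
  close at most `2 * jitter_m` of the gap, so this is precisely the
  condition under which planted trips are guaranteed recoverable, and
  the suite asserts *exact* per-user-day trip recovery.
- **Points**: every visited place emits `1 + Poisson(0.5)` points with
  coordinate jitter uniform in `[0, jitter_m]` (default 50 m, well below
  the 500 m clustering radius). Timestamps follow a double-peaked
  diurnal profile (morning and evening peaks) and are assigned in visit
  order; civil clock times are constructed directly in the analysis
  timezone, with times falling into the daylight-saving spring-forward
  gap pushed one hour later (parsers otherwise resolve them
  inconsistently, and a silently reordered point sequence fabricates
  trips).
- **Case surfaces**: weekly latent fields `u = ρWu + ε` (simultaneous
  autoregressive on the row-standardized queen weights, `|ρ| < 1`
  enforced), expectation `base_rate + b · ẑ(attractiveness) + u`, counts
  rounded and floored at zero by default (Poisson sampling optional;
  rounding keeps coupling recovery deterministic at small n).

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: demographic structure of who posts, home
locations weighted by population, road networks or realistic travel
chains, platform-specific spam patterns, retweet duplication, and zone
systems with irregular polygon geometry. The recovery results certify
the pipeline's algebra and bookkeeping, not the representativeness of
social-media mobility itself.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberately chosen scales:
parameter recovery at the study scale the generator defaults encode
(2000 users × 30 days ≈ 125k points, 64 zones), oracle equivalence on
25-zone grids where double loops are exact and fast, calibration over 50
replicates with 199 permutations, and everything else on grids of 9–144
zones. Oracle agreement is asserted at 1e-12 (pure floating-point
algebra), exact recovery at equality, recovery of stochastic parameters
at 3 Monte-Carlo standard errors, and distance recovery within
`2 * jitter_m` (the centroid displacement jitter can cause).

Degenerate inputs have defined behaviour rather than accidents: empty
point files warn and return typed empty tables; a single point is one
place; user-days with one place emit no trips; days without movers have
`m_rate = 0` and no `avg_dis`; constant variables error in Moran
statistics but NA-mark in the weekly suite; an edgeless network refuses
community detection; fewer than `k` usable profiles refuse clustering.
Ties are broken lexicographically by zone id wherever an order matters.

## Limitations

- Queen contiguity by shared vertices is exact only when touching
  polygons share vertices (always true for grids).
- The greedy modularity algorithm is deterministic but not globally
  optimal; the exhaustive-search test covers a small network only.
- Weekly suite p-values are reported raw, without multiple-testing
  correction across weeks — flagged here deliberately, since the suite
  is a monitoring dashboard rather than a confirmatory analysis.
- Cross-midnight displacements are never trips under the calendar-day
  convention; night-shift mobility is systematically invisible.
- Home-location inference, travel mode, routing and multi-day tours are
  out of scope.
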