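---
title: "Tracking fire events from half-daily active-fire detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking fire events from half-daily active-fire detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firetrackr)
```

## The model

`firetrackr` segments a stream of satellite active-fire pixel detections
into discrete, evolving fire events. The satellite observation process sets
the system's native clock: a polar-orbiting imager passes over mid-latitude
regions twice a day (about 1:30 am and 1:30 pm local time), so the tracker
advances in half-daily steps, each covering the local time window
[00:00, 12:00) (AM) or [12:00, 24:00) (PM). Acquisition times arrive in
UTC and are shifted by a fixed regional offset (no daylight-saving
adjustment, for determinism).

Each step applies the same pipeline:

1. **Filter**: keep detections of thermal-anomaly type 0 (presumed
   vegetation fire) inside the region of interest; in near-real-time mode
   additionally require nominal or high confidence, since the NRT product
   carries less quality assurance.
2. **Cluster**: group the step's pixels by single-linkage connected
   components under a linkage distance (default 1 km). The linkage value is
   not critical: it equals the smallest extended-area buffer, and a cluster
   split too finely self-heals at the merge stage.
3. **Assign**: each cluster attaches to the valid, *active* fire whose
   perimeter is nearest, provided that distance is within the fire's
   type-dependent extended-area buffer — 5 km for forest fires, 1 km for
   all other types, reflecting faster spread in forests. Ties go to the
   lower (older) fire id. Otherwise the cluster seeds a new fire object
   with the next sequential id; ids are issued in cluster order (clusters
   ordered by their first pixel in record order) so runs are reproducible.
   The cluster-to-fire distance is the minimum over the cluster's pixel
   points to the fire perimeter; measuring from the cluster's own hull
   instead changes distances by at most the cluster radius and did not
   change any scenario outcome we examined.
4. **Rebuild geometry** of changed fires (perimeter and active front).
5. **Merge**: if a fire changed at this step now lies within another
   active fire's extended area, all pixels of the higher-id fire (the
   *source*, with the later start date) move to the lower-id *target*; the
   source is flagged invalid and the (source, target) pair is recorded in
   the heritage list. The scan restarts after every merge (ascending
   source id) until a fixpoint, so chains A→B→C resolve deterministically
   with all pixels in the oldest fire. A merged source is emptied, never
   copied — the multiset of pixels over all fires always equals the
   ingested pixels.
6. **Static-source filter**: a fire smaller than 20 km² whose cumulative
   pixel density exceeds 20 px/km² is a persistent industrial heat source
   (gas flaring, landfills), not a spreading fire, and is invalidated.
   Because invalid fires stop receiving clusters, a persistent hotspot
   seeds a chain of short-lived objects, each invalidated in turn as soon
   as its density matures past the threshold; at any instant the only
   valid object near such a source is a freshly seeded one a few pixels
   old. Spreading fires stay far below the density threshold (about
   7–15 px/km² in our scenarios) because each burned patch is detected
   only while it is new.
7. **Activity update**: a valid fire with no new pixels for more than
   5 days — measured as more than 10 half-daily steps, the system's native
   unit — becomes inactive and is never reactivated; later detections
   nearby start new fires.
8. **Property refresh** for changed fires (area, perimeter, centroid,
   pixel density, mean FRP of the step's new pixels, fireline length,
   duration, land cover, fuel moisture, type).

## Perimeter delineation

The fire perimeter is the **alpha-shape concave hull** of all pixel
locations since ignition: the union of Delaunay triangles whose
circumradius is at most the disk radius α. The default α = 1 km balances
boundary fidelity against object fragmentation for 375 m-spaced
detections; as α → ∞ the shape converges to the convex hull. The hull is
expanded outward by a **187.5 m buffer** — half the nadir cross-track
pixel width — with round joins, so a detection's footprint contributes
area even at the perimeter. Degenerate counts use fallbacks: with exactly
three pixels (or any collinear configuration, where the alpha complex is
undefined) the buffered convex hull; with one or two pixels, circles of
radius 187.5 m around each pixel. A further guard: a pixel whose incident
triangles are all rejected by the alpha criterion (an isolated outlier)
would fall outside the pure alpha complex, so the hull unions a 187.5 m
disc around any such pixel — every input pixel is always inside its
fire's perimeter.

The **active fire front** is the subset of the perimeter within 500 m of
the pixels newly detected at the current step, computed exactly per
boundary segment (each new pixel contributes the solution interval of a
quadratic in the segment parameter) and joined into linestrings; a front
that wraps a whole ring is reported as a closed linear ring. Its length is
at most the perimeter length and every point of it lies on the perimeter.

### The geometry kernel and its numerics

All geometry is planar, on a spherical Albers equal-area projection
(default standard parallels 34°/40.5°, central meridian −120°, authalic
radius 6 370 997 m — appropriate for California; configurable for other
regions). Equal-area projection is required because metre-valued
thresholds and km² areas are used region-wide.

The kernel is self-contained:

* Delaunay triangulation is incremental Bowyer–Watson with a
  deterministic sub-micrometre index-hash perturbation that breaks the
  exact cocircularity of lattice-aligned detections; triangles are
  reported on the unperturbed coordinates, so areas are unaffected at the
  375 m pixel scale.
* The buffered perimeter is built as the union of one *capsule* (segment
  ⊕ disc) per hull edge; the alpha polygon itself enters the union through
  a point-membership test, since every point of its boundary is covered by
  a capsule. Union boundaries are extracted by an arrangement: piece edges
  are split at mutual intersections, fragments interior to the union are
  dropped, coincident fragments deduplicated (arcs are discretised on a
  shared global angular grid so coincident arcs are bitwise identical),
  and the survivors stitched into rings. Arc resolution defaults to 16
  segments per full circle for buffering (perimeter shortfall < 2 %,
  immaterial next to the ±1 pixel location uncertainty) and 128 for the
  one/two-pixel circle fallback (area accurate to 4 × 10⁻⁴ relative).
* Overlay areas (intersection-over-union, confusion matrices) clip one
  operand's rings against the other operand's convex decomposition with
  half-plane (Sutherland–Hodgman) clipping, whose enclosed signed area is
  exact even for concave subjects; holes are handled by the signed-ring
  convention (counter-clockwise positive, clockwise holes), for which
  inclusion–exclusion over ring pairs is exact. Decompositions are
  ear-clipping triangulations refined by convex differences; geometries
  are disjointified largest-first, which keeps nested footprint series
  cheap. Degenerate guards: clip edges shorter than 10⁻⁶ m define no
  half-plane; a clip ring with fewer than three real edges has no
  interior; convex pieces below 10⁻³ m² (the shoelace noise floor for
  metre-scale coordinates) are discarded.

## Attributes and classification

The dominant land cover is the modal class over grid cells whose centres
fall inside the perimeter (centroid-cell fallback for sub-cell fires; ties
break to the smaller class code). The classification table is:

| dominant cover      | FM-1000   | fire type       |
|---------------------|-----------|-----------------|
| forest              | ≥ 12 %    | forest wildfire |
| forest              | < 12 %    | forest management |
| shrub, grassland    | ≥ 12 %    | shrub wildfire  |
| shrub, grassland    | < 12 %    | shrub management |
| agriculture         | —         | agricultural    |
| urban               | —         | urban           |
| water, barren       | —         | other           |

FM-1000 is the 1000-hr dead fuel moisture (percent), sampled once per
fire, at the ignition-pixel centroid at the ignition step, from a coarse
(~4 km) field. The boundary at exactly 12 % is closed on the wildfire
side. Note a tension worth knowing about: prescribed burns tend to be set
under *moister* coarse fuels, yet this table assigns the high-moisture
side to wildfire. The table is implemented as printed; both the threshold
and its direction are exposed in `fed_config(fm_threshold,
fm_wildfire_ge)` so users can flip the convention. The dominant cover
(and with it the type) is re-evaluated at every step as the perimeter
grows; fixing it at ignition is the other defensible reading, but a large
fire's footprint is better characterised by what it has actually burned.

Land-cover and fuel-moisture grids are consumed as single-band rasters in
the plain-text ESRI ASCII grid format on the projected plane; the package
assumes the 7-class merge (water, urban, barren, forest, shrub, grassland,
agriculture) has been done upstream.

## Outputs and restartability

Four products mirror the detail-to-summary ladder: (i) a JSON state file
per step — an explicit, versioned schema with all doubles written at 17
significant digits, so `load_state(save_state(s))` is exactly `s` and a
run resumed from any checkpoint produces byte-identical downstream files;
(ii) GeoJSON snapshot layers (`perimeter`, `fireline`, `newfirepix`,
WGS84, valid fires only) named `YYYYMMDDAP_*`; (iii) a large-fire time
series for fires whose final area exceeds 4 km²; (iv) CSV season
summaries (per-step regional series, heritage list, large-fire ids). JSON
and GeoJSON were chosen over binary geodata containers to keep the package
dependency-free and the products diffable.

## The synthetic-data generator

The simulator is an *observation-process emulator*, not a fire-behaviour
model. A fire footprint grows as an ellipse with semi-axes
`k · rate_along × k · rate_cross` at step `k`, oriented by a wind
direction — chosen over cellular spread because closed-form footprints
give exact ground truth for area and overlap checks. The observation
process then: lays a 375 m lattice over the newly burned ring of each
step, keeps each node with detection probability 0.95 (detections are
occasionally lost to clouds, smoke and scan-angle effects), jitters kept
positions by a 50 m Gaussian (sub-pixel geolocation uncertainty), and
draws FRP from a log-normal (median 5 MW, σ_log 0.8 — small fires
dominate, rare large releases). Default growth is 400 × 200 m per
half-day over 12 steps, giving a ~37 km² fire of ~250 detections — a
mid-sized wildfire resolved well above the lattice scale. All randomness
derives from one seed per scenario.

What the simulator does *not* emulate: swath-angle-dependent pixel
growth, cloud gaps that are correlated in time, smoke-plume false
detections, unburned islands inside perimeters, or re-detection of
smouldering areas after the front passes (each lattice node is observable
only in the step its ring burns). Passing the end-to-end checks therefore
demonstrates that the object logic and geometry are correct under a
realistic detection geometry — not that real-data accuracy will match the
synthetic IoU (~0.95); against real reference perimeters the published
system's regional IoU is ~0.79.

Two scenario variants are used by the tests: a *static-hotspot* scenario
(1–3 detections per step at a fixed point, 60 m jitter) that must be
invalidated by the density rule while a concurrent spreading fire
survives; and a *merge* scenario of two ignitions exactly 1 km apart over
forest with slow growth (150 × 100 m per half-day) and a deterministic
observation process (detection probability 1, no jitter). The merge
scenario isolates the merging mechanics: the two ignitions must first
form separate objects — which requires their step-1 footprints to arrive
as distinct clusters — and then grow into one valid fire with a heritage
record; with the default fast growth their first-step footprints already
bridge the 1 km linkage and arrive as one cluster, and with stochastic
detection the separate-formation event would depend on whether each
ignition disc happens to contain a lattice node. Detection stochasticity
is exercised by the other scenarios.

## Scales and known limitations

The shipped tests and the acceptance script run scenarios of roughly
250–300 detections over 12–24 half-daily steps with single or paired
ignitions — sizes at which every geometric quantity can be cross-checked
against brute-force oracles (O(n⁴) Delaunay circumcircle enumeration,
union-find clustering, analytic ellipse areas). The tracker itself is
O(steps × pixels²) at worst (clustering and incremental triangulation)
and handles thousands of pixels per fire; regional multi-year runs are
feasible but the pure-R geometry kernel is not tuned for them.

Other limitations: one fire type per object per step (no mixtures); no
re-splitting of merged fires or retroactive pixel reassignment; the
187.5 m buffer does not grow with scan angle even though off-nadir pixels
are larger (up to ~470 m mean across the swath); unburned islands are not
carved out of hulls; per-fire accuracy is undefined (no per-fire region)
and is reported only regionally; the per-fire scores compare each
reference fire against the *union* of its overlapping tracked objects,
since one real fire often corresponds to several tracked objects.
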