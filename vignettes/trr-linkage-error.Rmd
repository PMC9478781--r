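---
title: "Deriving transplant referral regions and quantifying census-linkage error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving transplant referral regions and quantifying census-linkage error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trrlink)
```

## The problem

A transplant referral region (TRR) is the geographic catchment of a
transplant center, derived from where its waitlisted patients live. The
derivation chain runs through three mutually misaligned areal systems: zip
codes (postal, irregular), hospital referral regions (HRRs, market-based),
and census tracts/block groups (the units at which social-determinants data
exist). Linking census data to TRRs through zip crosswalks double-assigns
units that straddle TRR boundaries and ascribes area to the wrong region;
linking by direct spatial intersection cannot double-assign. This package
derives TRRs, runs both linkage methods, and measures each method's error.
Because the real inputs are restricted (registry waitlists) or bulky
(national shapefiles), the package ships a seeded generator of synthetic
study systems with the same structural pathologies, and every claim the
package makes is asserted on those systems by its test suite.

## Pipeline model and assumptions

**Cohort rules.** An entry is kept when its start date exists and does not
follow its recorded end date, and when at least one day (inclusive) of the
listing interval intersects the study period while the patient is an adult.
Missing end dates are read as "still active" and censored at the study end.
The rules are applied in a fixed, logged order — bad dates, censoring,
trimming, empty-interval exclusion — because the order determines only
which tally a doubly-defective row lands in, never the final cohort. Age
enters as interval trimming at the 18th birthday (computed with calendar
arithmetic; a Feb-29 birth maps to Feb 28), not as entry-level exclusion,
because the adult *portion* of the listing is what qualifies. A missing
birth date raises a data error rather than being silently kept or dropped.

**Center grouping.** Centers within 10 straight-line distance units of each
other merge, transitively: grouping is the connected components of the
threshold graph, so two far-apart centers linked by a middle center share a
group. Coordinates are planar by default; a lon/lat mode (great-circle
miles) exists behind a flag but the synthetic systems never use it.

**HRR assignment.** "Majority" is implemented as plurality (argmax over
distinct-patient counts): with more than two groups an absolute majority
need not exist, and the procedure is an argmax regardless. A patient counts
once per (HRR, group) however many entries they hold at that group's
centers, and counts for every group they are listed at. Count ties break to
the group whose representative point is nearest the HRR centroid, then to
the smallest group id; every tie is flagged in the output, because the
assignment must be deterministic and auditable. HRRs with zero waitlisted
patients join no TRR and are listed in the run manifest.

**Linkage.** The zip method keeps *every* tract→zip→HRR→TRR chain; no
deduplication to a dominant TRR is performed, since the duplicate
assignments are precisely the error being measured. Block groups inherit
their parent tract's TRR set. The spatial method first clips units to the
dissolved HRR coverage (dropping coastline-like slivers outside every HRR),
then assigns each unit to the TRR with the largest intersection area.

**Error metrics.** Per TRR, misassignment is the symmetric difference
between the TRR polygon and the union of its assigned (clipped) units,
decomposed into assigned-but-outside and uncovered components; the percent
is relative to TRR area and deliberately unclamped — a TRR whose assigned
units dwarf it exceeds 100%, which is information, not an artifact. For the
zip method a multiplet unit contributes its full geometry to every TRR it
reaches. Units unassigned by a method are excluded from that method's
metrics but reported. Methods are compared per scale by a paired Wilcoxon
signed-rank test on per-TRR percentages (zip minus spatial); zero
differences are dropped (the standard signed-rank convention; the count is
retained), the p-value is exact by full `2^n` sign enumeration up to n = 12
— which handles ties in the ranks exactly — and a tie- and
continuity-corrected normal approximation beyond.

## Geometry engine

No polygon-overlay dependency is used; the engine is part of the package
and is exact for the polygon class it handles (simple planar polygons,
optional holes):

* areas by the shoelace formula, holes subtracted;
* intersection areas by signed convex decomposition (convex rings kept
  whole, others ear-clipped; holes contribute negative pieces) and
  Sutherland–Hodgman clipping of piece pairs, with bounding-box pruning;
* union areas — needed when dissolve inputs may overlap — by a vertical
  slab decomposition cut at every vertex and edge-crossing x, where the
  per-slab union length at the slab midpoint integrates exactly;
* symmetric difference via the area identity
  `|AΔB| = |A| + |B| − 2|A∩B|`, with the intersection computed
  geometrically.

A dissolve keeps its member polygons and caches the exact union area.
Pipeline dissolves always union interior-disjoint tessellation members
(HRRs partition the region), for which piecewise intersection against the
members is exact; a dissolve of genuinely overlapping members is flagged
and refuses piecewise intersection rather than silently double-counting.

Numerical choices: ring validity (closure, ≥ 3 vertices, positive area,
no self-intersection) is checked at construction and errors name the
offending feature id. Half-plane clipping treats points within `1e-12` of
the boundary (relative to coordinate magnitude) as inside, so tessellation
neighbours that share exact vertices produce zero-area intersections, not
slivers. Crosswalk membership and spatial-assignment candidacy require an
overlap above `1e-9` of the unit's area; exact-tie spatial assignments go
to the smallest TRR id and are logged.

## What the synthetic generator emulates — and what it does not

The generator produces, from one seed (fanned out to per-layer subseeds so
adding a layer never perturbs earlier ones):

* an n×n block-group grid aggregated k×k into tracts (default 30×30 and
  k = 3 over a side-100 region: 900 block groups, 100 tracts) — exact
  nesting, as in census geography;
* h HRRs as Voronoi cells of random seed points (default 8), so HRR
  boundaries cut across census boundaries; seeds can be supplied to force
  the fully aligned limit;
* an m×m zip grid offset by a fraction δ of a cell (default 10×10, δ = 0.3,
  yielding 121 clipped cells), misaligned with both systems; crosswalks are
  derived from true polygon overlap, so split zips genuinely span several
  HRRs, the way real ZCTA crosswalks are built;
* centers placed sequentially, each with probability 0.3 within 10 units of
  an existing center (creating mergeable pairs), and waitlists (default
  2000 patients) whose center choice decays exponentially with distance
  (scale 15), with configurable rates of second-center listing (0.15),
  repeat entries (0.10), missing end dates (0.10), missing starts (0.02),
  reversed dates (0.02), under-18 overlap (0.05) and facility aliasing
  (0.2). Dates are drawn from a window one year wider than the study period
  on each side so every exclusion and censoring rule fires. Defaults were
  fixed once, as plausible rates for a registry-scale waitlist scaled to a
  desk-size region, before the comparison results were inspected.

Patient home location is the zip centroid — matching the lowest spatial
resolution the real data would offer. The generator does *not* emulate
population-weighted zip/tract sizes, coastline or water features, real HRR
shapes, or temporal zip redefinition. Consequently the tests demonstrate
the *structural* claims (zero multiplets under spatial linkage, spatial
misassignment never exceeding zip misassignment, exact agreement of both
methods in the aligned limit, count conservation) — not the magnitudes any
particular real geography would produce.

## Problem sizes and runtime

The test suite sweeps twenty seeds of the default system (900 block groups,
8 HRRs, δ = 0.3) for the structural guarantees, which keeps each full
pipeline run near a second; Monte-Carlo geometry cross-checks use 10⁶
sample points per fixture; exact signed-rank enumeration is checked against
brute force for every n ≤ 10. The aligned-limit fixture uses a 4×4
block-group grid with zip cells equal to tracts and HRR Voronoi seeds at
macro-cell centers, which puts every boundary of every layer on tract
lines.

## Known limitations

* Planar geometry only; the lon/lat flag affects point distances (center
  grouping), not polygon overlay. Projected coordinates are assumed for any
  real layers.
* The union-area slab algorithm requires hole-free members; pipeline
  dissolves satisfy this, but exotic user-supplied layers with holes can
  only be dissolved when interior-disjoint.
* The zip method's many-to-many chains are preserved end-to-end; a
  dominant-overlap deduplicated variant is out of scope, as is areal
  interpolation (splitting units across TRRs), which eliminates
  misassignment by construction but demands homogeneity or finer population
  data.
* With few TRRs the signed-rank p-value is bounded below (n = 7 pairs gives
  at best 2⁻⁶ ≈ 0.0156); desk-scale runs cannot reproduce registry-scale
  significance levels, only the ordering.
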