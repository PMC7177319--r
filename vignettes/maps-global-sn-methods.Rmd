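---
title: "Scoring and spatial methods for school-neighbourhood audits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and spatial methods for school-neighbourhood audits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snaudit)
```

# The assessment problem

Adolescents' active transport to school (walking or cycling) responds to
features of the school-neighbourhood built environment at two scales:
micro-scale streetscape attributes (sidewalk quality, crossing treatments,
aesthetics, bicycle facilities) observable only by in-person audit, and
macro-scale form (street connectivity, residential density, land-use mix)
computable from spatial data. `snaudit` implements the full computational
side of a school-neighbourhood audit campaign: it builds the audit sampling
frame from a street network, scores audit records through a hierarchical
scheme, computes macro-scale walkability metrics over the same catchment,
and supplies the reliability and concordance statistics used to validate a
condensed one-side-per-segment protocol.

# The audit sampling frame

## Street-network service area

The neighbourhood is the *street-network service area*: every network
location within a threshold shortest-path distance (default 500 m) of the
school's address point, snapped to the nearest road centreline (snap radius
50 m, a geocoding error beyond that). Distances are metric along the
network; all coordinates must be planar metric, projected upstream. Traversal
is undirected — one-way traffic restrictions do not bind pedestrians.
Coverage is computed per edge: an edge interval is covered when its shortest
network distance from the origin is within the threshold, so interior edges
are covered whole and frontier edges carry partial intervals. Coverage is
half-open: a segment touching the boundary at a single point is not in the
frame. Service areas are monotone in the threshold by construction, and the
test suite verifies interval membership against a brute-force
Floyd–Warshall oracle on toy graphs.

## Segments, sides, intersections

Street segments are maximal inter-junction road pieces: the GeoJSON reader
splits every LineString at junction points (shared endpoints or shared
interior vertices), so a road crossing three junctions yields two segments.
Each segment is audited on both street sides, labelled odd/even by
house-number parity of its address points; both sides exist regardless of
addressing (a side without addresses keeps its canonical parity label),
because the audit instrument requires two sides. Identifier codes follow the
compound convention `school.street.sequence[.O|.E]`.

Crossing audits are framed per intersection with at least three connecting
roads — degree-2 junctions are cartographic artefacts ("false"
intersections) and are excluded — with one audit per connecting road.

## Boundary protocol rules

Two rules regularise the frame at the buffer boundary:

1. **Exclusion.** A partially covered segment with no residence on either
   side is dropped from the audit and logged with its length.
2. **Extension.** A segment whose coverage enters from both ends is extended
   to one full segment when at least one residence lies in each covered end
   and the covered fraction strictly exceeds one half. "Majority of the
   length" is read as a strict `> 0.5` cut, so an exactly-half-covered
   segment does not extend — a documented, testable tie-break. No upper
   bound is placed on the bridged gap length; the gap is logged so users can
   filter.

A long-segment subdivision rule keeps audit pieces comparable: segments of
at most 200 m stay whole, 200–400 m are halved, 400–600 m are split in
thirds, and anything longer is cut into `ceiling(length / 200)` equal pieces
(our extrapolation of the halves/thirds pattern; pieces always sum to the
input length).

# The scoring model

Scoring is hierarchical: recoded item values sum into sub-scales, sub-scales
into valence section scores, and sections into an overall grand score.

* **Items** are integers in a declared raw range. A recode map (stored in
  the scheme, never in code) converts raw values to points; open-ended count
  items (e.g. number of street trees) carry a per-item cap.
* **Sub-scales** sum their member items' points and truncate at the
  sub-scale cap. Each item belongs to exactly one sub-scale. Negative
  sub-scales (litter, graffiti, crossing impediments, slope barriers) are
  capped first and then negated — the cap-then-negate order is a package
  decision where the convention is unstated.
* **Sections** are destinations & land use, positive streetscape, aesthetics
  & social (route audits), segment, and crossing. The **grand score** is the
  signed sum over all scored valence sub-scales; with the packaged default
  scheme its best-case value is 210 points.
* **Cross-domain sub-scales** (pedestrian infrastructure, max 27; pedestrian
  design, max 22; bicycle facilities, max 11) sum school-level item averages
  across sections. Their maxima are properties of the member items, attained
  exactly at best-case values.
* **Cul-de-sac amenities** are recorded but never scored.

The packaged scheme (`inst/extdata/maps_global_sn_default.yaml`) is this
package's own instrument: the published scoring hierarchy fixes the section
layout, the valence structure and the printed maxima (210/27/22/11), but not
the item-by-item coding, which lives in a separate coding document. The
default scheme therefore ships 104 items whose caps and ranges reproduce
those maxima exactly, and the loader validates any user scheme exhaustively
at load time: declared maxima must equal the achievable maxima computed by
best-case assignment, otherwise the scheme is rejected.

## School aggregation and side scopes

School-level sub-scale scores are unweighted means over audited units — the
aggregation the instrument describes; no length-weighting is applied.
Summaries can be computed per side scope (`odd`, `even`, `combined`) for the
condensed-protocol analysis. Crossing audits cannot be attributed to a side,
so the crossing component is shared verbatim across scopes (the tests check
bit-identity). Two crossing aggregation conventions exist in practice and
both are implemented: `crossing_unit = "audit"` (default) averages per
connecting-road audit, which makes the best-case school attain exactly the
210-point scheme maximum; `crossing_unit = "intersection"` first sums the
audits within each intersection, the convention used when reporting
per-intersection crossing scores. A missing section yields `NA` sections and
an `NA` grand score flagged incomplete — never a silent zero.

# Macro-scale metrics

* **Corridor area.** The denominator for densities is the union of
  fixed-radius corridors (default 95 m) around the covered centreline
  intervals. With no polygon-clipping library in the dependency set, the
  union is rasterised: a grid cell (default 2 m) belongs to the corridor
  when its centre is within the radius of any covered polyline. The
  discretisation error is of order resolution × perimeter; at 2 m it is
  about 1% for a typical neighbourhood, and the tests compare a straight
  corridor against the closed-form rectangle-plus-end-caps area.
* **Densities.** Junctions (or residences) per km² of corridor area; one
  residence per address point. One corridor area serves both densities and
  land use, with the radius configurable.
* **Land-use mix.** Normalised Shannon entropy of category proportions,
  `-Σ p_i ln p_i / ln k`, with `0·ln 0 := 0` and `k = 5` configured
  categories (residential, commercial, industrial, tertiary campus, open
  space) regardless of how many are locally present; `k = "present"` is
  available as the alternative. Proportions are measured by parcel area
  intersected with the corridor (rasterised point-in-polygon).
* **Walkability.** Per school, the sum of within-sample z-scores of the
  three components, using the sample standard deviation (n − 1; the small
  samples conventional in walkability work). The index has mean zero by
  construction; a zero-variance component contributes 0 with a warning, and
  a single school is an error.

# Reliability and concordance statistics

* **ICC.** Single-rater intraclass correlation from the one-way / two-way
  mean-square decomposition, with exact F-based 95% confidence intervals
  (Satterthwaite degrees of freedom for the agreement form). The default
  model is two-way random, absolute agreement — the conventional choice for
  two fixed-protocol auditors — with consistency and one-way forms selectable
  everywhere, including the command line. Negative CI bounds are reported as
  computed, not truncated: with very few targets the agreement interval is
  legitimately extreme. Zero between-target variance reports ICC 0 with a
  warning. Estimates are verified against an ANOVA sums-of-squares oracle
  over sweeps of small integer matrices.
* **Classification.** The reliability bands are excellent (ICC ≥ 0.75),
  good (0.60–0.74), fair (0.40–0.59), poor (< 0.40), boundaries inclusive
  as printed.
* **Correlation.** `correlate()` wraps `stats::cor.test`: Pearson by
  default, Spearman (average ranks, t-approximation) for designated
  non-normal measures — by default the destinations & land use and bicycle
  facilities scores. Constant input is an explicit error.
* **Concordance.** `concordance_inputs()` pairs odd- and even-scope school
  summaries into one row per school; `concordance()` reports per-measure
  odd/even correlation with means and SDs, and a combined-only crossing row
  (no correlation is possible for side-free crossing scores). The combined
  column is the equal-weight mean of the two sides.
* **Crossing-type shares** are percentages of crossing audits by
  intersection degree, reported to one decimal with the unrounded values
  retained (they sum to exactly 100).

The per-measure reliability report scores each audited unit for both raters
(section scores, per-unit grand contributions, cross-domain partial sums
from the items the unit kind carries) and computes the ICC over matched
units. The published tables this mirrors are ambiguous about the unit of
analysis behind some rows (routes versus schools), which is why their
extreme confidence bounds are not a target here; the report states its unit
counts explicitly.

# The synthetic-city generator

The generator makes every pipeline stage testable without external spatial
data. Its defaults are the study conditions the package is designed around,
chosen once:

* 12 schools on a 16 × 16 jittered grid with 115 m spacing — segment
  lengths near the ~114 m mean of audited urban segments; 6% of grid edges
  removed (connectivity preserved) for irregularity and dead ends.
* 4 residences per 100 m per street side, numbered odd/even by side —
  residential densities fall inside published urban school-neighbourhood
  ranges (roughly 60–1,300 residences/km²).
* A residential-dominant land-use mixture (85/6/3/2/4%) tiled in 150 m
  parcels, giving low-to-moderate per-school land-use mix.
* Audit items drawn by discretising latent Gaussians through quantile
  thresholds (latent mean −0.8, the sparse-streetscape regime), with
  between-side latent correlation ρ = 0.9 and second-rater latent noise
  SD 0.4 — producing the qualitative regime reported for urban co-audits:
  strong positive odd/even concordance and good-to-excellent ICCs.

Two caveats the generator makes explicit. First, discretisation to short
ordinal ranges attenuates the observable correlation below the latent ρ, so
recovery tests compare pipeline estimates against a large-sample Monte-Carlo
oracle that applies the same discretisation, not against raw ρ. Second, the
generator does not emulate topography, realistic cartography, spatially
clustered land use along arterials, or auditor drift over days — passing
tests demonstrate the computational pipeline, not field validity of any
particular audit campaign.

Determinism: one seed drives city generation, and per-school audit
generation derives a sub-seed (`seed × 1000 + school index`) so any school
is reproducible in isolation. Written GeoJSON is byte-deterministic.

# Problem sizes and numerical choices

The shipped test suite runs the full 12-school pipeline (a few thousand
audit rows), rasterises macro metrics at 8 m for the shared fixture and 1–2
m where areas are asserted against closed forms, sweeps ICC oracles over
hundreds of small matrices, and runs recovery at 500 targets and 2,000
correlation replicates — sizes chosen to exercise every code path at
interactive speed. Floating-point comparisons use strict tolerances (1e-10
for ICC-versus-oracle identity, 1–2% for rasterised areas). Interval
bookkeeping uses a 1e-9 m epsilon; segment coverage at exactly the threshold
distance yields zero-length intervals, which are dropped.

# Known limitations

* No polygon service-area ("no trim") variant: one corridor-union area
  serves all macro denominators, with the radius configurable.
* Rasterised areas converge at O(resolution); exact polygon unions would
  need a clipping dependency.
* The default scheme is a structurally faithful stand-in, not the
  proprietary item-by-item coding document; encode the real instrument in
  the same YAML format for production use.
* School-level score values from the original campaign are not reproducible
  — the underlying audit records are unpublished — and are not targets of
  the test suite; structure and statistics are.
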