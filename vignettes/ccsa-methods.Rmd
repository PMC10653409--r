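---
title: "Scoring fishery risk to blue-carbon habitats with ccsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring fishery risk to blue-carbon habitats with ccsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccsa)
```

## The model

Consequence and Spatial Analysis (CSA) is a semi-quantitative risk scoring
scheme for the impact of a fishery on benthic habitats. Each habitat type in
the assessed area is a *scoring element* carrying attribute scores in three
groups: habitat-productivity attributes (how sensitive the habitat is and
how slowly it recovers), gear–habitat interaction attributes (how strongly
the gear physically engages the habitat) and spatial attributes (how much of
the habitat the fishery touches). The three aggregation steps are

$$C = \frac{2\sum \text{productivity} + \sum \text{interaction}}{2\,n_{prod} + n_{inter}},
\qquad S = \left(\prod_{i=1}^{3} s_i\right)^{1/3},
\qquad \text{risk} = \sqrt{C^2 + S^2}.$$

The consequence score is a weighted mean with productivity attributes
counted twice — the only reading under which the documented score floor is
attainable: with every attribute at 1 it gives exactly $C = 1$, and together
with the minimal spatial triple (footprint 1, overlap 0.5, pressure 0.5,
whose geometric mean is $0.25^{1/3} \approx 0.63$) yields the published
low-risk endpoint $\sqrt{1 + 0.63^2} = 1.18$; the all-maximum configuration
yields $3\sqrt{2} = 4.24$. A plain unweighted mean over nine attributes
would give a floor of $13/9 \approx 1.44$ and could not reproduce 1.18, so
the package treats the weighted-mean form as the defined aggregation. The
risk score is the Euclidean distance of $(C, S)$ from the origin of the
two-axis risk plot; where a printed formula and that geometric definition
disagree, the geometric definition (which reproduces both endpoints) is
authoritative. Risk is kept at full precision internally and rounded to two
decimals only in human-facing tables.

The **carbon extension** changes two things relative to the baseline CSA:

- organic-carbon (OC) stock and OC accumulation enter as productivity
  attributes 3–4, so the productivity weight pool grows from 2 to 4
  attributes (the denominator from 9 to 13);
- the qualitative encounterability attribute is replaced by the
  quantitative swept-area-ratio (SAR) attribute.

An exact consequence of the weighted-mean form, verified by property tests:
the carbon-mode consequence exceeds the baseline one precisely when the mean
of the two OC scores exceeds the baseline consequence score. Habitats
storing more carbon than the assessment-wide average gain risk; carbon-poor
habitats lose it.

## Carbon attributes

Per-habitat OC stock (kg C m⁻², 1 m sediment-depth profile where relevant)
and OC accumulation (kg C m⁻² yr⁻¹, including macrophyte net primary
production where relevant) are consumed as published averages over the
management jurisdiction; the package deliberately does not re-derive them,
and detritus-export adjustments to accumulation are out of scope. Each
attribute may combine a sediment and a macrophyte component: records are
averaged within a component and the component means summed
(`combine_components()`).

Scores come from min–max normalization onto the continuous 1–3 range,
independently per attribute:

$$\text{score}(x) = 1 + 2\,\frac{x - \min}{\max - \min}.$$

Choices that matter here:

- **The pool is the full configured habitat table**, not just the habitats
  present in the assessed area, so scores are comparable across assessments
  within one jurisdiction.
- **A dummy 0.00 habitat** is included by default (`include_dummy = TRUE`)
  as a precautionary floor anchor: without it, the least carbon-rich *known*
  habitat would score 1 even if it held substantial carbon. Whether the
  dummy participates in both attributes or only stock is not settled by the
  published material; the flag applies it to both, and disabling it removes
  it from both.
- **Missing estimates (`n.d`) stay missing.** Habitats without OC data are
  excluded from carbon-mode assessment with a recorded reason; zero-filling
  would conflate "no data" with "no carbon".
- A degenerate pool (max = min) is an error rather than a silent constant.

`saltmarsh_sensitivity()` reruns carbon mode with the saltmarsh habitat —
typically the pool maximum, yet largely unfishable — removed from the pool.
Removing the maximum re-stretches the scale, so every remaining habitat's OC
score (and hence risk) can only increase; on the packaged fixture the
largest increase falls on the next-richest habitat (seagrass) and stays
below one and a half percent.

## Spatial attributes

**SAR.** The swept-area ratio of a 0.05° c-square is the number of times its
area is swept per year by mobile bottom-contacting gear; subsurface SAR
(penetration ≥ 2 cm) is the default field. Grid processing drops cells with
undisclosed values (removal, never zeroing — a zero means *observed absence
of effort*), clips cell centres to the jurisdiction boundary, and averages
multi-year values per cell. The scoring table divides $[0, \max \text{SAR}]$
into six equal-width intervals mapped to the six CSA bracket scores
0.5–3.0; intervals are half-open $[a, b)$ with the last closed so every
value in range maps to exactly one score, zero-effort cells land in the
first bracket and the maximum in the last. Equal-frequency (sextile) binning
is available behind `method = "equal_frequency"` for users who read "equal
intervals" distributionally. A habitat's SAR value is the area-weighted mean
over the cells its polygons intersect (stable under cell splitting and the
least assumption-laden aggregator; `max` is available for precautionary
runs). Gears that do not interact with the seabed short-circuit to the 0.5
floor.

**Overlap.** The spatial-overlap input is
$100 \cdot A(\text{habitat} \cap \text{fished}) / A(\text{habitat} \cap \text{jurisdiction})$.
The default six equal-width 16.67 % brackets mapping to 0.5–3.0 are an
editable stand-in (flagged in the configuration file) because the certified
bracket cut-points are not public; certification-faithful runs must override
them.

**Footprint.** Demersal trawls and dredges score 3; other gears score from
configuration with a floor of 1.

## Geometry

The package carries its own small planar-geometry layer: polygons are
matrices of WGS84 lon/lat vertices; areas are always computed in a
cylindrical equal-area projection (standard parallel at the data's mean
latitude — exact area preservation, which is the only property the scores
need); intersections use Sutherland–Hodgman clipping. Restrictions, asserted
or documented at each entry point: clip regions (grid cells, boundary
rectangles, Voronoi cells) must be convex; multi-part clip sets must not
self-overlap; interior rings (holes) are not supported. Vector I/O is
GeoJSON (FeatureCollections of Polygon/MultiPolygon features). These
restrictions fit every input the pipeline produces or consumes; maps with
holes must be pre-processed into hole-free parts.

## Synthetic data

The generator exists so the whole pipeline is testable without external
downloads, and doubles as a scenario engine:

- **Habitat mosaics** are seeded Voronoi tessellations of random points —
  gapless, non-overlapping convex polygons with EUNIS-level-3-style labels
  and littoral/sublittoral zones, exercising irregular-shape overlap and SAR
  aggregation.
- **SAR fields** place one cell per 0.05° lattice point. A configured
  fraction of cells (default 0.35) is exactly zero, mirroring the large
  untrawled share of real effort grids; positive values are log-normal
  (default meanlog 0, sdlog 1 — a long right tail, qualitatively like
  trawling-effort distributions) with optional variance-preserving Gaussian
  smoothing (default autocorrelation length 0.1°). Draws are keyed to
  global lattice coordinates by a counter-based 32-bit hash, so a fixed seed
  is reproducible bit-for-bit across platforms and clipping the extent
  never changes the surviving cells.
- **Carbon tables** draw per-habitat log-normal stock and accumulation
  means and mark a configured fraction of habitats `n.d`.

What the generator does not emulate: real effort grids are anisotropic
(effort follows bathymetry and ports), habitat maps have holes and
mixed-code polygons, and carbon estimates correlate with habitat type.
Passing synthetic tests therefore demonstrates the *scoring machinery* —
aggregation, normalization, exclusion, ranking — not the realism of any
particular case study.

The packaged case-study fixture (`case_study_fixture()`) carries the twelve
published habitat elements and UK-EEZ carbon table. Attribute values fixed
by published text (regeneration classes, the littoral/sublittoral
disturbance rule with the biogenic-reef override, the removability pair
under the dredge qualifier, footprint 3) are marked `source = "paper"`;
everything else (substratum profile, overlap, SAR, encounterability per
element) is a mid-range placeholder marked `source = "placeholder"`, because
the underlying per-element workbook is not publicly reproduced. Comparisons
computed from the fixture reproduce the published *signs and ordering* of
risk changes (seagrass the largest gain; sands and muds losing) but not the
exact published percentages, which depend on the unpublished spatial and
substratum scores.

## Numerical and design choices

- Regeneration brackets are half-open `[lower, upper)` with the decadal
  bracket closed below: exactly 1 year scores 2 and exactly 10 years
  scores 3.
- Natural-disturbance overrides are per-element configuration entries, not a
  shear-stress raster ingester; the zone rule plus overrides keeps the
  scorer data-free.
- Rank ties are broken by ascending element id, making comparison reports
  deterministic.
- Attribute weighting beyond the ×2 productivity factor is deliberately not
  exposed in the standard interface; subjective weights are withheld until
  the carbon-impact evidence base matures.
- Test and example problem sizes (≤ 1000-cell grids, ≤ 24-patch mosaics,
  10⁴-pair numeric oracles) were chosen as the smallest sizes at which every
  property under test is non-trivially exercised.
- Run outputs are byte-deterministic for identical configurations; the run
  manifest (configuration echo plus input checksums) is sufficient to replay
  a run exactly.

## Limitations

- The MSC lookup-table cells not reproduced in public sources (substratum
  profile for gears other than dredge/trawl, overlap and encounterability
  brackets) ship as flagged, editable stand-ins; results under the defaults
  are methodologically faithful but not certification-grade.
- Risk is uniform across a habitat's range; within-habitat effort gradients
  require splitting elements upstream.
- No conversion to MSC performance-indicator scores, no greenhouse-gas
  accounting: the output is a relative risk ranking, not an emissions
  estimate.
- OC burial rates and carbon lability — which modulate how much disturbed
  carbon is actually remineralized — are not yet attributes.
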