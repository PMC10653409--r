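# Default CSA scoring tables.
#
# Entries marked `standin: true` cover cells of the MSC FCP v2.2 lookup
# tables (PF14-PF17) that are not public in the sources this package draws
# on; they are editable defaults, not certified MSC values, and should be
# overridden for certification-faithful runs.
gears:
  demersal-trawl:
    bottom_contacting: true
  dredge:
    bottom_contacting: true
  hand-collection:
    bottom_contacting: true
  non-bottom-contacting:
    bottom_contacting: false

# Regeneration-of-biota brackets (years to recover after disturbance).
# Half-open [lower, upper); the decadal bracket is closed below.
regeneration_brackets:
  - {upper_years: 1, score: 1}
  - {upper_years: 10, score: 2}
  - {upper_years: .inf, score: 3}

# Natural disturbance by depth zone (littoral = intertidal/shallow subtidal).
natural_disturbance:
  littoral: 1
  sublittoral: 2

# Removability of biota, per gear.
removability_biota:
  demersal-trawl: 3
  dredge: 3
  hand-collection: {score: 1, standin: true}

# Removability of substratum, per gear x substratum-hardness category.
removability_substratum:
  demersal-trawl: {hard: 1, soft: 3, sediment: 3}
  dredge: {hard: 1, soft: 3, sediment: 3}
  hand-collection: {hard: 1, soft: 1, sediment: 1, standin: true}

# Substratum hardness / ruggedness / seabed slope, per gear. Higher scores
# mark terrain more workable by (hence more exposed to) the gear.
substratum_profile:
  demersal-trawl:
    hardness: {hard: 1, soft: 2, sediment: 3}
    ruggedness: {high-relief: 1, low-relief: 2, flat: 3}
    slope: {low: 3, medium: 2, high: 1}
    standin: true
  dredge:
    hardness: {hard: 1, soft: 2, sediment: 3}
    ruggedness: {high-relief: 1, low-relief: 2, flat: 3}
    slope: {low: 3, medium: 2, high: 1}
    standin: true
  hand-collection:
    hardness: {hard: 1, soft: 1, sediment: 1}
    ruggedness: {high-relief: 1, low-relief: 1, flat: 1}
    slope: {low: 1, medium: 1, high: 1}
    standin: true

# Gear footprint: demersal trawls and dredges carry the largest footprint.
gear_footprint:
  demersal-trawl: 3
  dredge: 3
  hand-collection: {score: 1, standin: true}
  non-bottom-contacting: {score: 1, standin: true}

# Spatial-overlap brackets (percentage of habitat range inside the fished
# area). Six equal-width brackets; stand-in for the MSC PF7.5.4 cut-points.
overlap_brackets:
  - {upper_pct: 16.666667, score: 0.5}
  - {upper_pct: 33.333333, score: 1.0}
  - {upper_pct: 50.0, score: 1.5}
  - {upper_pct: 66.666667, score: 2.0}
  - {upper_pct: 83.333333, score: 2.5}
  - {upper_pct: 100.0, score: 3.0}
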