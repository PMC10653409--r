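# Attribute vocabulary. Productivity attributes are double-weighted in the
# consequence score; the OC pair exists only in carbon mode, and the SAR /
# encounterability pair are mode-specific spatial attributes.
PRODUCTIVITY_BASE <- c("regeneration", "natural_disturbance")
PRODUCTIVITY_CARBON <- c(PRODUCTIVITY_BASE, "oc_stock", "oc_accumulation")
INTERACTION_ATTRS <- c("removability_biota", "removability_substratum",
                       "substratum_hardness", "substratum_ruggedness",
                       "seabed_slope")
SPATIAL_ATTRS <- c("gear_footprint", "spatial_overlap", "sar", "encounterability")
OC_ATTRS <- c("oc_stock", "oc_accumulation")

#' Legal range of a CSA attribute score
#'
#' Consequence attributes (productivity and gear-habitat interaction) lie in
#' \[1, 3\]; only the organic-carbon pair may be non-integer. Spatial
#' attributes lie in \[0.5, 3\].
#'
#' @param attribute Attribute name.
#' @return Numeric length-2 range.
#' @export
attribute_range <- function(attribute) {
  if (attribute %in% SPATIAL_ATTRS) c(0.5, 3) else c(1, 3)
}

validate_attribute_score <- function(attribute, value) {
  if (!is_scalar_number(value))
    abort_validation("attribute '%s': score must be a single finite number", attribute)
  rng <- attribute_range(attribute)
  if (value < rng[1] || value > rng[2])
    abort_validation("attribute '%s': score %.4g outside legal range [%g, %g]",
                     attribute, value, rng[1], rng[2])
  discrete <- attribute %in% c(PRODUCTIVITY_BASE, INTERACTION_ATTRS)
  if (discrete && !value %in% c(1, 2, 3))
    abort_validation("attribute '%s': score must be one of 1, 2, 3 (got %.4g)",
                     attribute, value)
  invisible(value)
}

#' Create a scoring element
#'
#' A scoring element is one distinct habitat type under assessment, carrying
#' its depth zone, optional substratum categories (used by the gear-habitat
#' lookup scorers), optional polygon geometry, and a named vector of attribute
#' scores accumulated as the attributes are scored.
#'
#' @param element_id Integer identifier (used for deterministic tie-breaks).
#' @param habitat_label Habitat name (EUNIS level-3 style).
#' @param zone `"littoral"` or `"sublittoral"`.
#' @param substratum Optional named list with `hardness`
#'   (`hard`/`soft`/`sediment`), `ruggedness` (`high-relief`/`low-relief`/
#'   `flat`) and `slope` (`low`/`medium`/`high`).
#' @param scores Named numeric vector of attribute scores already assigned.
#' @param geometry Optional list of polygon matrices (lon/lat columns).
#' @return A `ccsa_element` object.
#' @export
scoring_element <- function(element_id, habitat_label, zone,
                            substratum = NULL, scores = numeric(0),
                            geometry = NULL) {
  if (!zone %in% c("littoral", "sublittoral"))
    abort_validation("zone must be 'littoral' or 'sublittoral' (got '%s')", zone)
  if (length(scores) > 0) {
    if (is.null(names(scores)) || any(names(scores) == ""))
      abort_validation("scores must be a named vector")
    if (anyDuplicated(names(scores)))
      abort_validation("element %s: attribute '%s' assigned more than once",
                       element_id, names(scores)[duplicated(names(scores))][1])
    for (a in names(scores)) validate_attribute_score(a, scores[[a]])
  }
  structure(
    list(element_id = as.integer(element_id), habitat_label = habitat_label,
         zone = zone, substratum = substratum, scores = scores,
         geometry = geometry),
    class = "ccsa_element"
  )
}

#' @export
print.ccsa_element <- function(x, ...) {
  cat(sprintf("<ccsa_element %d> %s (%s)\n", x$element_id, x$habitat_label, x$zone))
  if (length(x$scores)) {
    cat("  scores:", paste(sprintf("%s=%.4g", names(x$scores), x$scores),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

set_scores <- function(element, ...) {
  new <- c(...)
  for (a in names(new)) {
    validate_attribute_score(a, new[[a]])
    element$scores[[a]] <- new[[a]]
  }
  element
}

#' Score the regeneration-of-biota attribute
#'
#' Habitats recovering in under a year score 1; between one year (inclusive)
#' and a decade score 2; decadal or longer recovery scores 3. Brackets are
#' half-open `[lower, upper)` so the decadal bracket is closed below.
#'
#' @param recovery_time Estimated recovery time after disturbance, in years.
#' @param tables Scoring tables.
#' @return Attribute score in \{1, 2, 3\}.
#' @export
#' @examples
#' score_regeneration(0.5)  # fast-recovering infaunal sediments -> 1
#' score_regeneration(2.5)  # kelp understorey -> 2
#' score_regeneration(15)   # saltmarsh, seagrass -> 3
score_regeneration <- function(recovery_time, tables = read_scoring_tables()) {
  if (!is_scalar_number(recovery_time) || recovery_time <= 0)
    abort_validation("recovery_time must be a positive number of years")
  b <- tables$regeneration_brackets
  idx <- which(recovery_time < b$upper_years)[1]
  if (is.na(idx)) idx <- nrow(b)
  b$score[idx]
}

#' Score the natural-disturbance attribute
#'
#' Littoral (intertidal and shallow subtidal) habitats experience more natural
#' disturbance and score 1; sublittoral habitats score 2. Per-element
#' overrides express site-specific evidence (e.g. a reef lying wholly within a
#' high-disturbance area) without attaching a disturbance raster.
#'
#' @param element A [scoring_element()].
#' @param overrides Optional named vector/list mapping element_id to a score
#'   in \{1, 2, 3\}.
#' @param tables Scoring tables.
#' @return Attribute score in \{1, 2, 3\}.
#' @export
score_natural_disturbance <- function(element, overrides = NULL,
                                      tables = read_scoring_tables()) {
  key <- as.character(element$element_id)
  if (!is.null(overrides) && key %in% names(overrides)) {
    val <- as.numeric(overrides[[key]])
    if (!val %in% c(1, 2, 3))
      abort_validation("natural-disturbance override for element %s must be 1, 2 or 3",
                       key)
    return(val)
  }
  as.numeric(tables$natural_disturbance[[element$zone]])
}

#' Score the five gear-habitat interaction attributes
#'
#' Looks up removability of biota, removability of substratum, substratum
#' hardness, substratum ruggedness and seabed slope for a gear against the
#' element's substratum categories.
#'
#' @param element A [scoring_element()] with `substratum` categories set.
#' @param gear A [gear_type()].
#' @param tables Scoring tables.
#' @return Named numeric vector of the five interaction scores.
#' @export
score_gear_interaction <- function(element, gear, tables = read_scoring_tables()) {
  sub <- element$substratum
  if (is.null(sub) || is.null(sub$hardness) || is.null(sub$ruggedness) ||
      is.null(sub$slope))
    abort_validation("element %s has no substratum categories (hardness/ruggedness/slope)",
                     element$element_id)

  lookup <- function(section, key, label) {
    val <- section[[key]]
    if (is.null(val))
      abort_config("no scoring-table entry for %s '%s' (gear '%s')",
                   label, key, gear$name)
    cell_score(val, key)
  }

  rb_sec <- tables$removability_biota
  if (is.null(rb_sec[[gear$name]]))
    abort_config("no scoring-table entry for removability_biota gear '%s'", gear$name)
  rb <- cell_score(rb_sec[[gear$name]], gear$name)

  rs_sec <- tables$removability_substratum[[gear$name]]
  if (is.null(rs_sec))
    abort_config("no scoring-table entry for removability_substratum gear '%s'", gear$name)
  rs <- lookup(rs_sec, sub$hardness, "removability_substratum hardness")

  prof <- tables$substratum_profile[[gear$name]]
  if (is.null(prof))
    abort_config("no scoring-table entry for substratum_profile gear '%s'", gear$name)
  scores <- c(
    removability_biota = as.numeric(rb),
    removability_substratum = as.numeric(rs),
    substratum_hardness = as.numeric(lookup(prof$hardness, sub$hardness, "hardness")),
    substratum_ruggedness = as.numeric(lookup(prof$ruggedness, sub$ruggedness, "ruggedness")),
    seabed_slope = as.numeric(lookup(prof$slope, sub$slope, "seabed slope"))
  )
  for (a in names(scores)) validate_attribute_score(a, scores[[a]])
  scores
}
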