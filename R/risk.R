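#' Consequence score: weighted mean of consequence attributes
#'
#' The consequence score is the mean of the habitat-productivity and
#' gear-habitat interaction attribute scores with the productivity attributes
#' double-weighted:
#' `C = (2 * sum(productivity) + sum(interaction)) / (2 * n_prod + n_inter)`.
#' With every attribute at 1 this gives exactly C = 1, the floor that makes
#' the published risk range attainable. Baseline mode carries 2 productivity
#' attributes (regeneration, natural disturbance); carbon mode carries 4
#' (adding OC stock and OC accumulation).
#'
#' @param productivity Named or unnamed numeric vector of productivity
#'   attribute scores (length 2 or 4), each in \[1, 3\].
#' @param interaction Numeric vector of the 5 interaction scores, each in
#'   \[1, 3\].
#' @return Consequence score in \[1, 3\].
#' @export
#' @examples
#' consequence_score(c(1, 2), c(3, 3, 1, 1, 1))
consequence_score <- function(productivity, interaction) {
  if (!length(productivity) %in% c(2L, 4L))
    abort_validation("expected 2 (baseline) or 4 (carbon) productivity scores, got %d",
                     length(productivity))
  if (length(interaction) != 5L)
    abort_validation("expected 5 gear-habitat interaction scores, got %d",
                     length(interaction))
  vals <- c(productivity, interaction)
  if (any(!is.finite(vals)) || any(vals < 1) || any(vals > 3))
    abort_validation("consequence attribute scores must lie in [1, 3]")
  (2 * sum(productivity) + sum(interaction)) /
    (2 * length(productivity) + length(interaction))
}

#' Spatial score: geometric mean of the three spatial attributes
#'
#' @param footprint Gear-footprint score in \[1, 3\].
#' @param overlap Spatial-overlap score in \[0.5, 3\].
#' @param sar SAR (or, baseline mode, encounterability) score in \[0.5, 3\].
#' @return Spatial score `(footprint * overlap * sar)^(1/3)`.
#' @export
spatial_score <- function(footprint, overlap, sar) {
  vals <- c(footprint, overlap, sar)
  if (length(vals) != 3 || any(!is.finite(vals)) || any(vals <= 0))
    abort_validation("spatial_score needs three positive scores")
  if (any(vals < 0.5) || any(vals > 3))
    abort_validation("spatial attribute scores must lie in [0.5, 3]")
  prod(vals)^(1 / 3)
}

#' Overall CSA risk score
#'
#' The Euclidean distance of the (consequence, spatial) pair from the origin
#' of the two-axis risk plot: `risk = sqrt(C^2 + S^2)`. Over the legal
#' attribute ranges (with footprint at least 1) it spans 1.18 (low risk) to
#' 4.24 (high risk) at two decimals. Full precision is retained; rounding is
#' applied only in human-facing tables.
#'
#' @param consequence Consequence score (> 0).
#' @param spatial Spatial score (> 0).
#' @return The CSA risk score.
#' @export
#' @examples
#' round(csa_risk(3, 3), 2)  # 4.24
csa_risk <- function(consequence, spatial) {
  if (!is_scalar_number(consequence) || !is_scalar_number(spatial) ||
      consequence <= 0 || spatial <= 0)
    abort_validation("consequence and spatial scores must be positive numbers")
  sqrt(consequence^2 + spatial^2)
}

#' Assess scoring elements in baseline or carbon mode
#'
#' Baseline mode scores each element with 2 productivity attributes and the
#' qualitative encounterability spatial attribute; carbon mode injects the
#' normalized OC stock and accumulation scores as productivity attributes 3-4
#' and uses the quantitative SAR attribute. Elements whose habitat lacks
#' carbon estimates are excluded from carbon mode (with the reason recorded
#' in the `excluded` attribute of the result), never imputed.
#'
#' Each element must already carry its attribute scores (see
#' [scoring_element()]); the gear-footprint score is taken from the element if
#' present, else from the gear via [score_footprint()].
#'
#' @param elements List of [scoring_element()] objects.
#' @param tables Scoring tables.
#' @param gear A [gear_type()].
#' @param mode `"baseline"` or `"carbon"`.
#' @param carbon_scores A `ccsa_carbon_scores` table (required in carbon mode).
#' @return A `ccsa_risk` data.frame (`element_id`, `habitat_label`, `mode`,
#'   `consequence`, `spatial`, `risk`) ordered by `element_id`, with attribute
#'   `excluded` listing carbon-mode exclusions.
#' @export
assess <- function(elements, tables = read_scoring_tables(), gear,
                   mode = c("baseline", "carbon"), carbon_scores = NULL) {
  mode <- match.arg(mode)
  if (mode == "carbon" && is.null(carbon_scores))
    abort_validation("carbon mode requires a carbon_scores table (see normalize_carbon)")

  excluded <- data.frame(element_id = integer(0), habitat_label = character(0),
                         reason = character(0))
  rows <- list()
  for (e in elements) {
    s <- e$scores
    need_base <- c(PRODUCTIVITY_BASE, INTERACTION_ATTRS)
    miss <- setdiff(need_base, names(s))
    if (length(miss) > 0)
      abort_validation("element %d ('%s') is missing attribute score(s): %s",
                       e$element_id, e$habitat_label, paste(miss, collapse = ", "))

    prod_scores <- unname(s[PRODUCTIVITY_BASE])
    if (mode == "carbon") {
      row <- carbon_scores[carbon_scores$habitat_label == e$habitat_label, , drop = FALSE]
      if (nrow(row) == 0 || is.na(row$stock_score[1]) || is.na(row$accumulation_score[1])) {
        reason <- if (nrow(row) == 0) "habitat absent from carbon table"
                  else "no OC stock/accumulation estimate (n.d)"
        excluded <- rbind(excluded, data.frame(
          element_id = e$element_id, habitat_label = e$habitat_label,
          reason = reason))
        next
      }
      prod_scores <- c(prod_scores, row$stock_score[1], row$accumulation_score[1])
    }

    footprint <- if ("gear_footprint" %in% names(s)) s[["gear_footprint"]]
                 else score_footprint(gear, tables)
    overlap <- s[["spatial_overlap"]]
    if (is.null(overlap) || is.na(overlap))
      abort_validation("element %d ('%s') has no spatial_overlap score",
                       e$element_id, e$habitat_label)
    pressure_attr <- if (mode == "carbon") "sar" else "encounterability"
    pressure <- s[[pressure_attr]]
    if (is.null(pressure) || is.na(pressure))
      abort_validation("element %d ('%s') has no %s score",
                       e$element_id, e$habitat_label, pressure_attr)

    C <- consequence_score(prod_scores, unname(s[INTERACTION_ATTRS]))
    S <- spatial_score(footprint, overlap, pressure)
    rows[[length(rows) + 1L]] <- data.frame(
      element_id = e$element_id, habitat_label = e$habitat_label, mode = mode,
      consequence = C, spatial = S, risk = csa_risk(C, S))
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(element_id = integer(0), habitat_label = character(0),
                         mode = character(0), consequence = numeric(0),
                         spatial = numeric(0), risk = numeric(0))
  out <- out[order(out$element_id), , drop = FALSE]
  rownames(out) <- NULL
  excluded <- excluded[order(excluded$element_id), , drop = FALSE]
  rownames(excluded) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("ccsa_risk", "data.frame")
  out
}

#' Compare baseline and carbon-mode risk results
#'
#' Joins the two result sets on element, computes the signed percent change
#' `100 * (carbon - baseline) / baseline`, ranks each mode by descending risk
#' (ties broken by ascending element id), and summarizes the largest increase
#' and decrease. Elements excluded from carbon mode appear with `NA` carbon
#' columns.
#'
#' @param baseline Baseline-mode `ccsa_risk` results.
#' @param carbon Carbon-mode `ccsa_risk` results.
#' @param subset Optional habitat labels over which the mean percent change is
#'   summarized (defaults to all dually-scored habitats).
#' @return A `ccsa_comparison` data.frame with a `summary` attribute.
#' @export
compare_modes <- function(baseline, carbon, subset = NULL) {
  b <- as.data.frame(baseline)[, c("element_id", "habitat_label", "consequence",
                                   "spatial", "risk")]
  c_ <- as.data.frame(carbon)[, c("element_id", "consequence", "spatial", "risk")]
  m <- merge(b, c_, by = "element_id", all.x = TRUE,
             suffixes = c("_baseline", "_carbon"))
  m$percent_change <- 100 * (m$risk_carbon - m$risk_baseline) / m$risk_baseline

  rank_desc <- function(risk, id) {
    ord <- order(-risk, id)
    rk <- integer(length(risk)); rk[ord] <- seq_along(ord)
    rk
  }
  m$rank_baseline <- rank_desc(m$risk_baseline, m$element_id)
  scored <- !is.na(m$risk_carbon)
  m$rank_carbon <- NA_integer_
  m$rank_carbon[scored] <- rank_desc(m$risk_carbon[scored], m$element_id[scored])
  m <- m[order(m$element_id), , drop = FALSE]
  rownames(m) <- NULL

  pc <- m$percent_change[scored]
  labs <- m$habitat_label[scored]
  sub_idx <- if (is.null(subset)) rep(TRUE, sum(scored)) else labs %in% subset
  attr(m, "summary") <- list(
    largest_increase = if (any(scored)) labs[which.max(pc)] else NA_character_,
    largest_increase_pct = if (any(scored)) max(pc) else NA_real_,
    largest_decrease = if (any(scored)) labs[which.min(pc)] else NA_character_,
    largest_decrease_pct = if (any(scored)) min(pc) else NA_real_,
    mean_percent_change = if (any(sub_idx)) mean(pc[sub_idx]) else NA_real_
  )
  attr(m, "excluded") <- attr(carbon, "excluded")
  class(m) <- c("ccsa_comparison", "data.frame")
  m
}

#' @export
print.ccsa_comparison <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, ...)
  s <- attr(x, "summary")
  if (!is.null(s) && !is.na(s$largest_increase))
    cat(sprintf("largest increase: %s (%+.2f%%); largest decrease: %s (%+.2f%%)\n",
                s$largest_increase, s$largest_increase_pct,
                s$largest_decrease, s$largest_decrease_pct))
  invisible(x)
}
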