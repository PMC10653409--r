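#' Read a per-habitat organic-carbon table
#'
#' The CSV has one row per habitat x component with columns `habitat_label`,
#' `component` (`sediment`, `macrophyte`, or `combined` for pre-summed
#' values), `oc_stock_kgCm2` and `oc_accumulation_kgCm2yr`. Missing estimates
#' are written `n.d` (or left empty) and are kept as explicit missing values,
#' never zero-filled: a habitat without data is excluded from carbon-mode
#' assessment rather than treated as carbon-free.
#'
#' @param path CSV path. The packaged UK-EEZ average table (1 m sediment depth
#'   profile, macrophyte biomass included where relevant) is read when omitted.
#' @return A data.frame of component records.
#' @export
read_carbon_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "carbon_uk_eez.csv",
                                package = "ccsa", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(habitat_label = "character",
                                       component = "character",
                                       oc_stock_kgCm2 = "character",
                                       oc_accumulation_kgCm2yr = "character"))
  need <- c("habitat_label", "component", "oc_stock_kgCm2", "oc_accumulation_kgCm2yr")
  if (!all(need %in% names(df)))
    abort_validation("carbon table must have columns: %s", paste(need, collapse = ", "))
  parse_nd <- function(x) {
    x <- trimws(x)
    x[x %in% c("n.d", "nd", "NA", "")] <- NA
    as.numeric(x)
  }
  df$oc_stock_kgCm2 <- parse_nd(df$oc_stock_kgCm2)
  df$oc_accumulation_kgCm2yr <- parse_nd(df$oc_accumulation_kgCm2yr)
  df
}

#' Combine sediment and macrophyte carbon components per habitat
#'
#' Each carbon attribute is a single value built from up to two components:
#' sediment organic carbon and macrophyte biomass carbon. Records are averaged
#' within a component and the component means summed, independently for stock
#' and accumulation. Habitats whose records are all missing stay missing
#' (`NA`), flagging them for exclusion rather than scoring.
#'
#' @param records Component records as returned by [read_carbon_table()].
#' @return A `ccsa_carbon` data.frame with one row per habitat and columns
#'   `habitat_label`, `oc_stock`, `oc_accumulation`.
#' @export
#' @examples
#' recs <- data.frame(
#'   habitat_label = c("mud", "mud"), component = c("sediment", "macrophyte"),
#'   oc_stock_kgCm2 = c(2.0, 0.5), oc_accumulation_kgCm2yr = c(0.02, 0.01))
#' combine_components(recs)
combine_components <- function(records) {
  if (nrow(records) == 0) abort_validation("carbon table has no records")
  bad <- !is.na(records$oc_stock_kgCm2) & records$oc_stock_kgCm2 < 0 |
    !is.na(records$oc_accumulation_kgCm2yr) & records$oc_accumulation_kgCm2yr < 0
  if (any(bad))
    abort_validation("negative organic-carbon value for habitat '%s'",
                     records$habitat_label[bad][1])

  combine_one <- function(values, components) {
    ok <- !is.na(values)
    if (!any(ok)) return(NA_real_)
    means <- tapply(values[ok], components[ok], mean)
    sum(means)
  }
  habitats <- unique(records$habitat_label)
  out <- data.frame(
    habitat_label = habitats,
    oc_stock = vapply(habitats, function(h) {
      r <- records[records$habitat_label == h, ]
      combine_one(r$oc_stock_kgCm2, r$component)
    }, numeric(1)),
    oc_accumulation = vapply(habitats, function(h) {
      r <- records[records$habitat_label == h, ]
      combine_one(r$oc_accumulation_kgCm2yr, r$component)
    }, numeric(1)),
    row.names = NULL
  )
  class(out) <- c("ccsa_carbon", "data.frame")
  out
}

DUMMY_LABEL <- "Unknown low carbon capacity habitat"

#' Normalize carbon estimates to the 1-3 attribute scoring range
#'
#' Organic-carbon stock and accumulation are mapped independently onto the
#' continuous 1-3 attribute scale by min-max normalization over the habitat
#' pool: `score(x) = 1 + 2 (x - min) / (max - min)`. The pool is the full
#' configured habitat table (jurisdiction-wide averages), optionally including
#' a precautionary dummy habitat at 0.00 stock and accumulation that anchors
#' the scale floor, so that a genuinely low-carbon habitat never scores as the
#' pool minimum by accident. Habitats with missing estimates receive no score.
#'
#' @param carbon A `ccsa_carbon` table (see [combine_components()]).
#' @param include_dummy Include the 0.00 dummy habitat in the pool (default
#'   `TRUE`). If no row labelled `dummy_label` exists one is added.
#' @param exclude Optional habitat labels dropped from both the pool and the
#'   output (used by the saltmarsh sensitivity analysis).
#' @param dummy_label Label identifying the dummy habitat row.
#' @return A `ccsa_carbon_scores` data.frame (`habitat_label`, `stock_score`,
#'   `accumulation_score`) with a `normalization` attribute recording the
#'   min/max used, the dummy flag and any exclusions.
#' @export
normalize_carbon <- function(carbon, include_dummy = TRUE, exclude = NULL,
                             dummy_label = DUMMY_LABEL) {
  df <- as.data.frame(carbon)
  if (!is.null(exclude)) df <- df[!df$habitat_label %in% exclude, , drop = FALSE]
  has_dummy <- dummy_label %in% df$habitat_label
  if (include_dummy && !has_dummy) {
    df <- rbind(df, data.frame(habitat_label = dummy_label,
                               oc_stock = 0, oc_accumulation = 0))
  } else if (!include_dummy && has_dummy) {
    df <- df[df$habitat_label != dummy_label, , drop = FALSE]
  }

  norm_one <- function(x, what) {
    ok <- !is.na(x)
    if (sum(ok) < 2 || length(unique(x[ok])) < 2)
      abort_degenerate("cannot normalize %s: fewer than two distinct values in pool", what)
    rng <- range(x[ok])
    list(score = ifelse(ok, 1 + 2 * (x - rng[1]) / (rng[2] - rng[1]), NA_real_),
         min = rng[1], max = rng[2])
  }
  st <- norm_one(df$oc_stock, "OC stock")
  ac <- norm_one(df$oc_accumulation, "OC accumulation")

  out <- data.frame(habitat_label = df$habitat_label,
                    stock_score = st$score,
                    accumulation_score = ac$score,
                    row.names = NULL)
  attr(out, "normalization") <- list(
    stock = c(min = st$min, max = st$max),
    accumulation = c(min = ac$min, max = ac$max),
    include_dummy = include_dummy, dummy_label = dummy_label,
    excluded = exclude %||% character(0)
  )
  class(out) <- c("ccsa_carbon_scores", "data.frame")
  out
}

#' Saltmarsh-exclusion sensitivity analysis
#'
#' Saltmarsh typically holds the pool-maximum carbon estimates while being
#' largely out of reach of towed gear; including it compresses every other
#' habitat's carbon score. This analysis reruns the carbon-mode assessment
#' with saltmarsh removed from the normalization pool (and from the element
#' set) and reports the per-habitat risk change.
#'
#' @param elements List of scoring elements ready for carbon-mode assessment
#'   (see [assess()]).
#' @param carbon A `ccsa_carbon` table.
#' @param gear A [gear_type()].
#' @param tables Scoring tables.
#' @param saltmarsh_label Habitat label to exclude.
#' @param include_dummy Passed to [normalize_carbon()].
#' @return Data.frame with per-habitat risk scores with and without saltmarsh
#'   in the pool, and the signed percentage change.
#' @export
saltmarsh_sensitivity <- function(elements, carbon, gear,
                                  tables = read_scoring_tables(),
                                  saltmarsh_label = "Coastal saltmarshes and saline reedbeds",
                                  include_dummy = TRUE) {
  scores_with <- normalize_carbon(carbon, include_dummy = include_dummy)
  scores_without <- normalize_carbon(carbon, include_dummy = include_dummy,
                                     exclude = saltmarsh_label)
  with_res <- assess(elements, tables = tables, gear = gear, mode = "carbon",
                     carbon_scores = scores_with)
  elements_wo <- Filter(function(e) e$habitat_label != saltmarsh_label, elements)
  without_res <- assess(elements_wo, tables = tables, gear = gear, mode = "carbon",
                        carbon_scores = scores_without)

  m <- merge(with_res[, c("element_id", "habitat_label", "risk")],
             without_res[, c("element_id", "risk")],
             by = "element_id", suffixes = c("_with", "_without"))
  m$percent_change <- 100 * (m$risk_without - m$risk_with) / m$risk_with
  m[order(m$element_id), , drop = FALSE]
}
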