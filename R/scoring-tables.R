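#' Read a CSA scoring-table configuration
#'
#' Scoring tables encode the MSC-style lookup tables used by the attribute
#' scorers: regeneration brackets, the natural-disturbance zone rule,
#' removability of biota and substratum per gear, the substratum
#' hardness/ruggedness/slope profile, gear footprint, and spatial-overlap
#' brackets. They ship as editable YAML so that lookup cells not fixed by the
#' published sources can be overridden; such default cells are flagged
#' `standin: true` in the file and recorded in the returned object.
#'
#' @param path Path to a YAML file. The packaged default is used when omitted.
#' @return A `ccsa_tables` object (a validated list).
#' @export
#' @examples
#' tbl <- read_scoring_tables()
#' names(tbl$gears)
read_scoring_tables <- function(path = NULL) {
  path <- path %||% system.file("extdata", "scoring_tables_default.yaml",
                                package = "ccsa", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  as_scoring_tables(raw)
}

# Accept either a bare number or {score: x, standin: true} in config cells.
cell_score <- function(x, key) {
  if (is.list(x)) {
    if (is.null(x$score)) abort_config("config cell '%s' has no 'score' field", key)
    x$score
  } else {
    x
  }
}

as_scoring_tables <- function(raw) {
  required <- c("gears", "regeneration_brackets", "natural_disturbance",
                "removability_biota", "removability_substratum",
                "substratum_profile", "gear_footprint", "overlap_brackets")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    abort_config("scoring-table config is missing section(s): %s",
                 paste(missing, collapse = ", "))

  tbl <- raw
  tbl$regeneration_brackets <- do.call(rbind, lapply(raw$regeneration_brackets, function(b) {
    data.frame(upper_years = as.numeric(b$upper_years), score = as.numeric(b$score))
  }))
  tbl$overlap_brackets <- do.call(rbind, lapply(raw$overlap_brackets, function(b) {
    data.frame(upper_pct = as.numeric(b$upper_pct), score = as.numeric(b$score))
  }))

  if (is.unsorted(tbl$regeneration_brackets$upper_years, strictly = TRUE) ||
      is.unsorted(tbl$regeneration_brackets$score, strictly = TRUE))
    abort_config("regeneration brackets must be strictly increasing in bound and score")
  if (is.unsorted(tbl$overlap_brackets$upper_pct, strictly = TRUE) ||
      is.unsorted(tbl$overlap_brackets$score, strictly = TRUE))
    abort_config("overlap brackets must be strictly increasing in bound and score")
  if (abs(tbl$overlap_brackets$upper_pct[nrow(tbl$overlap_brackets)] - 100) > 1e-6)
    abort_config("overlap brackets must cover [0, 100]")

  zones <- names(tbl$natural_disturbance)
  if (!all(c("littoral", "sublittoral") %in% zones))
    abort_config("natural_disturbance must score both 'littoral' and 'sublittoral'")

  for (g in names(tbl$gears)) {
    if (is.null(tbl$gears[[g]]$bottom_contacting))
      abort_config("gear '%s' has no bottom_contacting field", g)
  }

  structure(tbl, class = "ccsa_tables")
}

#' @export
print.ccsa_tables <- function(x, ...) {
  cat("<ccsa_tables>\n")
  cat("  gears:", paste(names(x$gears), collapse = ", "), "\n")
  cat("  regeneration brackets:", nrow(x$regeneration_brackets), "\n")
  cat("  overlap brackets:", nrow(x$overlap_brackets), "\n")
  invisible(x)
}

#' Construct a gear type from the configured vocabulary
#'
#' @param name Gear name as configured (e.g. `"dredge"`, `"demersal-trawl"`,
#'   `"non-bottom-contacting"`).
#' @param tables Scoring tables (see [read_scoring_tables()]).
#' @return A `ccsa_gear` list with `name` and `bottom_contacting`.
#' @export
gear_type <- function(name, tables = read_scoring_tables()) {
  if (!name %in% names(tables$gears))
    abort_config("gear '%s' is not in the configured gear vocabulary (%s)",
                 name, paste(names(tables$gears), collapse = ", "))
  structure(
    list(name = name,
         bottom_contacting = isTRUE(tables$gears[[name]]$bottom_contacting)),
    class = "ccsa_gear"
  )
}
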