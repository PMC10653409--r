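#' Read and validate a run configuration
#'
#' A run configuration (YAML) binds the inputs of an assessment: the mode
#' (`baseline`, `carbon` or `both`), paths to the habitat map (GeoJSON),
#' SAR grid (CSV), carbon table (CSV), attribute-score table (CSV), scoring
#' tables (YAML), jurisdiction and fished-area boundaries (GeoJSON), the gear
#' name, SAR years, and the flags `include_dummy`, `exclude_saltmarsh`,
#' `sar_binning` (`equal_width`/`equal_frequency`) and `sar_aggregator`
#' (`mean`/`max`).
#'
#' @param path YAML file path.
#' @return A validated `ccsa_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- dirname(normalizePath(path))
  as_run_config(cfg)
}

as_run_config <- function(cfg) {
  cfg$mode <- match.arg(cfg$mode %||% "both", c("baseline", "carbon", "both"))
  cfg$gear <- cfg$gear %||% "dredge"
  cfg$include_dummy <- cfg$include_dummy %||% TRUE
  cfg$exclude_saltmarsh <- isTRUE(cfg$exclude_saltmarsh)
  cfg$sar_binning <- match.arg(cfg$sar_binning %||% "equal_width",
                               c("equal_width", "equal_frequency"))
  cfg$sar_aggregator <- match.arg(cfg$sar_aggregator %||% "mean", c("mean", "max"))
  if (is.null(cfg$scores))
    abort_config("run config needs 'scores': the element attribute-score CSV")
  if (cfg$mode != "baseline" && is.null(cfg$carbon_table))
    abort_config("mode '%s' requires a carbon_table", cfg$mode)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p) && !is.null(cfg$base_dir))
      p <- file.path(cfg$base_dir, p)
    if (!file.exists(p)) abort_config("input path does not exist: %s", p)
    p
  }
  for (key in c("scores", "carbon_table", "habitat_map", "sar_grid",
                "jurisdiction", "fished_area", "tables"))
    cfg[[key]] <- resolve(cfg[[key]])
  structure(cfg, class = "ccsa_config")
}

#' Run a full assessment from a configuration
#'
#' Loads every configured input, computes the spatial attributes from data
#' where geometry and a SAR grid are supplied (falling back to the scores
#' table otherwise), runs the requested mode(s), and writes to the output
#' directory: `results.csv` (full precision), `comparison.csv` (mode
#' `both`), `risk_map.geojson` (when a habitat map is supplied) and
#' `manifest.json` (configuration echo, package version, input checksums).
#' On error all partial outputs are removed.
#'
#' @param config A `ccsa_config` (see [read_run_config()]) or a list of the
#'   same fields.
#' @param out Output directory (created if needed).
#' @return Invisibly, a list with the result tables and written paths.
#' @export
run_assessment <- function(config, out = config$out %||% ".") {
  if (!inherits(config, "ccsa_config")) config <- as_run_config(config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    tables <- read_scoring_tables(config$tables)
    gear <- gear_type(config$gear, tables)
    scores <- utils::read.csv(config$scores, stringsAsFactors = FALSE)
    elements <- elements_from_scores(scores)

    map <- if (!is.null(config$habitat_map)) read_habitat_map(config$habitat_map)
    jurisdiction <- if (!is.null(config$jurisdiction))
      unlist(lapply(read_habitat_map(config$jurisdiction)$features, `[[`, "polygons"),
             recursive = FALSE)
    fished <- if (!is.null(config$fished_area))
      unlist(lapply(read_habitat_map(config$fished_area)$features, `[[`, "polygons"),
             recursive = FALSE)

    grid <- intervals <- NULL
    if (!is.null(config$sar_grid)) {
      records <- read_sar_csv(config$sar_grid)
      grid <- load_sar_grid(records, years = config$years, boundary = jurisdiction)
      intervals <- build_sar_intervals(grid, method = config$sar_binning)
    }

    # data-driven spatial attributes where geometry is available
    if (!is.null(map)) {
      elements <- lapply(elements, function(e) {
        geom <- map_geometry(map, e$habitat_label)
        if (length(geom) == 0) return(e)
        e$geometry <- geom
        if (!is.null(fished) && !is.null(jurisdiction)) {
          pct <- compute_overlap(geom, fished, jurisdiction)
          e$scores[["spatial_overlap"]] <- score_overlap(pct, tables)
        }
        if (!is.null(grid)) {
          e$scores[["sar"]] <- score_sar(geom, grid, intervals, gear,
                                         aggregator = config$sar_aggregator)
        }
        e
      })
    }

    results <- list()
    if (config$mode %in% c("baseline", "both"))
      results$baseline <- assess(elements, tables, gear, mode = "baseline")
    if (config$mode %in% c("carbon", "both")) {
      carbon <- combine_components(read_carbon_table(config$carbon_table))
      exclude <- if (config$exclude_saltmarsh)
        "Coastal saltmarshes and saline reedbeds"
      carbon_scores <- normalize_carbon(carbon,
                                        include_dummy = config$include_dummy,
                                        exclude = exclude)
      els <- elements
      if (!is.null(exclude))
        els <- Filter(function(e) !e$habitat_label %in% exclude, els)
      results$carbon <- assess(els, tables, gear, mode = "carbon",
                               carbon_scores = carbon_scores)
    }

    results_path <- file.path(out, "results.csv")
    utils::write.csv(do.call(rbind, lapply(results, as.data.frame)),
                     results_path, row.names = FALSE)
    written <- c(written, results_path)

    comparison <- NULL
    if (config$mode == "both") {
      comparison <- compare_modes(results$baseline, results$carbon)
      cmp_path <- file.path(out, "comparison.csv")
      utils::write.csv(as.data.frame(comparison), cmp_path, row.names = FALSE)
      written <- c(written, cmp_path)
    }

    if (!is.null(map)) {
      lab <- vapply(map$features, `[[`, "", "habitat_label")
      pick <- function(res) {
        if (is.null(res)) return(rep(NA_real_, length(lab)))
        res$risk[match(lab, res$habitat_label)]
      }
      extra <- data.frame(risk_baseline = pick(results$baseline),
                          risk_carbon = pick(results$carbon))
      map_path <- file.path(out, "risk_map.geojson")
      write_habitat_map(map, map_path, extra = extra)
      written <- c(written, map_path)
    }

    inputs <- Filter(Negate(is.null),
                     config[c("scores", "carbon_table", "habitat_map",
                              "sar_grid", "jurisdiction", "fished_area", "tables")])
    manifest <- list(
      config = unclass(config)[setdiff(names(config), "base_dir")],
      package = "ccsa",
      package_version = as.character(utils::packageVersion("ccsa")),
      inputs = lapply(inputs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))))
    manifest_path <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, manifest_path)

    invisible(list(results = results, comparison = comparison, paths = written))
  }, error = on_fail)
}

#' Reclassify mixed habitat codes on a map
#'
#' Habitat polygons classified with mixed codes (labels containing `/` or
#' `+` by default) are relabelled following a reclassification table. A mixed
#' code mapped to several target labels duplicates the polygon once per
#' target, leaving every polygon's geometry unchanged. Mixed codes absent
#' from the table raise a validation error naming them.
#'
#' @param map A `ccsa_map`.
#' @param reclass Data.frame with columns `mixed_code`, `habitat_label` and
#'   optionally `zone`.
#' @param mixed_pattern Regular expression identifying mixed codes.
#' @param dissolve Merge all polygons sharing a final label into a single
#'   feature (one scoring element per habitat).
#' @return The reclassified `ccsa_map`.
#' @export
reclassify_habitats <- function(map, reclass, mixed_pattern = "[+/]",
                                dissolve = FALSE) {
  if (!all(c("mixed_code", "habitat_label") %in% names(reclass)))
    abort_validation("reclassification table needs columns mixed_code, habitat_label")
  labels <- vapply(map$features, `[[`, "", "habitat_label")
  mixed <- grepl(mixed_pattern, labels)
  unmapped <- setdiff(labels[mixed], reclass$mixed_code)
  if (length(unmapped) > 0)
    abort_validation("unmapped mixed habitat code(s): %s",
                     paste(unique(unmapped), collapse = "; "))

  features <- list()
  for (f in map$features) {
    hits <- reclass[reclass$mixed_code == f$habitat_label, , drop = FALSE]
    if (nrow(hits) == 0) {
      features[[length(features) + 1L]] <- f
    } else {
      for (i in seq_len(nrow(hits))) {
        g <- f
        g$habitat_label <- hits$habitat_label[i]
        if ("zone" %in% names(hits) && !is.na(hits$zone[i]))
          g$zone <- hits$zone[i]
        features[[length(features) + 1L]] <- g
      }
    }
  }
  out <- structure(list(features = features), class = "ccsa_map")
  if (dissolve) out <- dissolve_map(out)
  out
}

# One feature per habitat label, polygons concatenated.
dissolve_map <- function(map) {
  labels <- vapply(map$features, `[[`, "", "habitat_label")
  features <- lapply(unique(labels), function(lab) {
    fs <- map$features[labels == lab]
    list(habitat_label = lab, zone = fs[[1]]$zone,
         polygons = unlist(lapply(fs, `[[`, "polygons"), recursive = FALSE),
         properties = list())
  })
  structure(list(features = features), class = "ccsa_map")
}
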