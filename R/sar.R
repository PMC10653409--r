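#' Read a c-square swept-area-ratio CSV
#'
#' Columns: `cell_id`, `lon`, `lat` (cell-centre degrees, WGS84), `year`,
#' `surface_sar`, `subsurface_sar`. Undisclosed values are written `n.d` or
#' left empty and become `NA` (they are removed, never zeroed, by
#' [load_sar_grid()]).
#'
#' @param path CSV path.
#' @return Data.frame of raw records.
#' @export
read_sar_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "lon", "lat", "year", "surface_sar", "subsurface_sar")
  if (!all(need %in% names(df)))
    abort_validation("SAR CSV must have columns: %s", paste(need, collapse = ", "))
  for (col in c("surface_sar", "subsurface_sar")) {
    x <- trimws(as.character(df[[col]]))
    x[x %in% c("n.d", "nd", "NA", "")] <- NA
    df[[col]] <- as.numeric(x)
  }
  df
}

#' Build a swept-area-ratio grid from c-square records
#'
#' Filters to the requested years, drops records with undisclosed (missing)
#' SAR values, clips cell centres to a boundary polygon, and averages
#' multi-year values per cell. Subsurface SAR (gear penetration >= 2 cm) is
#' the default field, matching the penetration depths of mobile
#' bottom-contacting gear; surface SAR is selectable.
#'
#' @param records Data.frame from [read_sar_csv()] (or equivalent).
#' @param years Optional integer vector of years to retain.
#' @param boundary Optional boundary geometry (polygon matrix or list);
#'   cells whose centres fall outside are dropped.
#' @param field `"subsurface"` (default) or `"surface"`.
#' @param resolution Cell size in degrees (c-squares: 0.05).
#' @return A `ccsa_sar_grid`: data.frame (`cell_id`, `lon`, `lat`, `sar`) with
#'   a `resolution` attribute. Cell footprints are the half-open squares
#'   centred on (`lon`, `lat`).
#' @export
load_sar_grid <- function(records, years = NULL, boundary = NULL,
                          field = c("subsurface", "surface"),
                          resolution = 0.05) {
  field <- match.arg(field)
  col <- paste0(field, "_sar")
  df <- records
  if (!is.null(years)) df <- df[df$year %in% years, , drop = FALSE]
  df <- df[!is.na(df[[col]]), , drop = FALSE]          # undisclosed: removed
  if (!is.null(boundary)) {
    keep <- point_in_geom(df$lon, df$lat, boundary)
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0)
    ccsa_abort("ccsa_empty_grid_error",
               "no SAR cells remain after year filtering/clipping")
  if (any(df[[col]] < 0))
    abort_validation("negative SAR value in cell '%s'",
                     df$cell_id[df[[col]] < 0][1])
  agg <- stats::aggregate(df[[col]],
                          by = list(cell_id = df$cell_id, lon = df$lon, lat = df$lat),
                          FUN = mean)
  names(agg)[4] <- "sar"
  agg <- agg[order(agg$cell_id), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, resolution = resolution,
            class = c("ccsa_sar_grid", "data.frame"))
}

#' Build the six-interval SAR scoring table
#'
#' Divides the grid's SAR distribution into six intervals mapped onto the six
#' CSA bracket scores 0.5, 1.0, ..., 3.0 in increasing order. The default is
#' six equal-width intervals over \[0, max SAR\]; equal-frequency (sextile)
#' binning of the positive values is available behind `method`.
#' Intervals are half-open `[a, b)` with the final interval closed above, so
#' zero-effort cells fall in the first interval and the maximum maps to 3.
#'
#' @param grid A `ccsa_sar_grid`.
#' @param method `"equal_width"` (default) or `"equal_frequency"`.
#' @return A `ccsa_intervals` data.frame (`lower`, `upper`, `score`).
#' @export
build_sar_intervals <- function(grid, method = c("equal_width", "equal_frequency")) {
  method <- match.arg(method)
  if (nrow(grid) == 0) ccsa_abort("ccsa_empty_grid_error", "empty SAR grid")
  mx <- max(grid$sar)
  if (mx <= 0)
    abort_degenerate("all SAR values are zero; interval table would be degenerate")
  breaks <- if (method == "equal_width") {
    seq(0, mx, length.out = 7)
  } else {
    pos <- grid$sar
    qs <- stats::quantile(pos, probs = seq(0, 1, length.out = 7), names = FALSE)
    qs[1] <- 0; qs[7] <- mx
    if (any(diff(qs) <= 0))
      abort_degenerate("SAR distribution too concentrated for equal-frequency intervals")
    qs
  }
  out <- data.frame(lower = breaks[1:6], upper = breaks[2:7],
                    score = seq(0.5, 3, by = 0.5))
  structure(out, class = c("ccsa_intervals", "data.frame"))
}

#' Look up the bracket score for a SAR value
#'
#' @param x SAR value(s) within \[0, max\] of the table.
#' @param intervals A `ccsa_intervals` table.
#' @return Bracket score(s).
#' @export
interval_score <- function(x, intervals) {
  if (any(x < intervals$lower[1] - 1e-12) ||
      any(x > intervals$upper[nrow(intervals)] + 1e-12))
    abort_validation("SAR value outside the interval table range [%g, %g]",
                     intervals$lower[1], intervals$upper[nrow(intervals)])
  idx <- findInterval(x, intervals$lower, rightmost.closed = FALSE)
  idx[idx > nrow(intervals)] <- nrow(intervals)
  idx[idx < 1L] <- 1L
  intervals$score[idx]
}

# Cell footprint polygons and area weights for a habitat geometry.
cell_weights <- function(geometry, grid) {
  r <- attr(grid, "resolution")
  if (is.matrix(geometry)) geometry <- list(geometry)
  lat_ts <- mean(unlist(lapply(geometry, function(p) p[, 2])))
  w <- vapply(seq_len(nrow(grid)), function(i) {
    cell <- rect_poly(grid$lon[i] - r / 2, grid$lat[i] - r / 2,
                      grid$lon[i] + r / 2, grid$lat[i] + r / 2)
    intersection_area_m2(geometry, list(cell), lat_ts = lat_ts)
  }, numeric(1))
  w
}

#' Score the swept-area-ratio attribute for a habitat
#'
#' Gears that do not interact with the seabed receive the lowest SAR bracket
#' score of 0.5 regardless of geometry. Otherwise the habitat's SAR is
#' aggregated over the grid cells its geometry intersects (area-weighted mean
#' by default, maximum as an option) and looked up in the interval table.
#'
#' @param geometry Habitat geometry (polygon matrix or list).
#' @param grid A `ccsa_sar_grid`.
#' @param intervals A `ccsa_intervals` table.
#' @param gear A [gear_type()].
#' @param aggregator `"mean"` (area-weighted, default) or `"max"`.
#' @return Attribute score in \{0.5, 1, 1.5, 2, 2.5, 3\}.
#' @export
score_sar <- function(geometry, grid, intervals, gear,
                      aggregator = c("mean", "max")) {
  aggregator <- match.arg(aggregator)
  if (!gear$bottom_contacting) return(0.5)
  w <- cell_weights(geometry, grid)
  if (all(w <= 0))
    ccsa_abort("ccsa_no_pressure_error",
               "habitat geometry intersects no SAR cells (bottom-contacting gear)")
  value <- if (aggregator == "mean") {
    sum(w * grid$sar) / sum(w)
  } else {
    max(grid$sar[w > 0])
  }
  interval_score(value, intervals)
}

#' Score the spatial-overlap attribute
#'
#' @param pct Overlap percentage in \[0, 100\] (see [compute_overlap()]).
#' @param tables Scoring tables (the ordered overlap brackets).
#' @return Bracket score in \[0.5, 3\].
#' @export
score_overlap <- function(pct, tables = read_scoring_tables()) {
  if (!is_scalar_number(pct) || pct < 0 || pct > 100)
    abort_validation("overlap percentage must lie in [0, 100]")
  b <- tables$overlap_brackets
  idx <- which(pct < b$upper_pct)[1]
  if (is.na(idx)) idx <- nrow(b)
  b$score[idx]
}

#' Score the gear-footprint attribute
#'
#' Demersal trawls and dredges carry the largest spatial footprint and score
#' 3; other gears score from configuration (minimum 1).
#'
#' @param gear A [gear_type()].
#' @param tables Scoring tables.
#' @return Footprint score in \[1, 3\].
#' @export
score_footprint <- function(gear, tables = read_scoring_tables()) {
  cell <- tables$gear_footprint[[gear$name]]
  if (is.null(cell))
    abort_config("no gear_footprint entry for gear '%s'", gear$name)
  max(1, as.numeric(cell_score(cell, gear$name)))
}
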