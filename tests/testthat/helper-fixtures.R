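# Shared builders for small in-code fixtures.

default_tables <- read_scoring_tables()
dredge <- gear_type("dredge", default_tables)
trawl <- gear_type("demersal-trawl", default_tables)
pelagic <- gear_type("non-bottom-contacting", default_tables)

# A bare element with every consequence + spatial attribute set to `value`
# (spatial pair at `spatial`), suitable for direct assess() calls.
make_element <- function(id = 1L, habitat = "Sublittoral sand",
                         zone = "sublittoral", consequence = 1,
                         footprint = 1, overlap = 0.5, pressure = 0.5) {
  scoring_element(id, habitat, zone, scores = c(
    regeneration = consequence, natural_disturbance = consequence,
    removability_biota = consequence, removability_substratum = consequence,
    substratum_hardness = consequence, substratum_ruggedness = consequence,
    seabed_slope = consequence,
    gear_footprint = footprint, spatial_overlap = overlap,
    sar = pressure, encounterability = pressure))
}

# Unit square polygon [x0, x0+w] x [y0, y0+w] (degrees).
square <- function(x0, y0, w = 1) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + w, y0 + w))
}

# Exact area of a lon/lat-aligned rectangle under any equal-area projection.
rect_area_exact <- function(lon0, lat0, lon1, lat1) {
  R <- 6371008.8
  R^2 * (lon1 - lon0) * pi / 180 * (sin(lat1 * pi / 180) - sin(lat0 * pi / 180))
}

# A tiny SAR grid from explicit cells.
make_grid <- function(lon, lat, sar, resolution = 0.05) {
  structure(data.frame(cell_id = sprintf("c%02d", seq_along(lon)),
                       lon = lon, lat = lat, sar = sar),
            resolution = resolution,
            class = c("ccsa_sar_grid", "data.frame"))
}

# Random legal consequence/spatial attribute sets for property tests.
random_scores <- function(n, mode = "carbon") {
  n_prod <- if (mode == "carbon") 4 else 2
  lapply(seq_len(n), function(i) {
    prod_disc <- sample(1:3, 2, replace = TRUE)
    prod_oc <- if (mode == "carbon") stats::runif(2, 1, 3) else NULL
    list(productivity = c(prod_disc, prod_oc),
         interaction = sample(1:3, 5, replace = TRUE),
         spatial = c(stats::runif(1, 1, 3), stats::runif(2, 0.5, 3)))
  })
}
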