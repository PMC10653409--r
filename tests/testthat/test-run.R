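# Build a complete synthetic run (all input files) in a directory.
write_demo_inputs <- function(dir, seed = 23) {
  sc <- synthetic_scenario(seed = seed, extent = c(0, 54, 1, 55),
                           n_habitats = 4, n_patches = 12)
  map <- generate_habitat_mosaic(sc)
  grid <- generate_sar_field(sc)
  carbon <- generate_carbon_table(sc)
  carbon$oc_stock_kgCm2[2] <- NA  # one n.d habitat exercises exclusion

  write_habitat_map(map, file.path(dir, "habitat_map.geojson"))
  utils::write.csv(
    data.frame(cell_id = grid$cell_id, lon = grid$lon, lat = grid$lat,
               year = 2015L, surface_sar = grid$sar, subsurface_sar = grid$sar),
    file.path(dir, "sar_grid.csv"), row.names = FALSE)
  utils::write.csv(carbon, file.path(dir, "carbon_table.csv"), row.names = FALSE)

  rect_map <- function(x0, y0, x1, y1) {
    structure(list(features = list(list(
      habitat_label = "boundary", zone = "sublittoral",
      polygons = list(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))),
      properties = list()))), class = "ccsa_map")
  }
  write_habitat_map(rect_map(0, 54, 1, 55), file.path(dir, "jurisdiction.geojson"))
  write_habitat_map(rect_map(0.2, 54.2, 0.9, 54.9), file.path(dir, "fished.geojson"))

  rows <- do.call(rbind, lapply(seq_along(sc$habitat_labels), function(i) {
    lab <- sc$habitat_labels[i]
    data.frame(element_id = i, habitat_label = lab,
               zone = ifelse(grepl("^(Littoral|Coastal)", lab),
                             "littoral", "sublittoral"),
               attribute = c("regeneration", "natural_disturbance",
                             "removability_biota", "removability_substratum",
                             "substratum_hardness", "substratum_ruggedness",
                             "seabed_slope", "gear_footprint",
                             "spatial_overlap", "sar", "encounterability"),
               value = c(1, 1, 3, 3, 2, 2, 2, 3, 2, 2, 2))
  }))
  utils::write.csv(rows, file.path(dir, "scores.csv"), row.names = FALSE)

  list(mode = "both", gear = "dredge",
       scores = file.path(dir, "scores.csv"),
       carbon_table = file.path(dir, "carbon_table.csv"),
       habitat_map = file.path(dir, "habitat_map.geojson"),
       sar_grid = file.path(dir, "sar_grid.csv"),
       jurisdiction = file.path(dir, "jurisdiction.geojson"),
       fished_area = file.path(dir, "fished.geojson"),
       years = 2015L)
}

test_that("a full run writes results, comparison, risk map and manifest", {
  dir <- withr::local_tempdir()
  cfg <- write_demo_inputs(dir)
  out <- file.path(dir, "out")
  res <- run_assessment(cfg, out = out)
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "comparison.csv")))
  expect_true(file.exists(file.path(out, "risk_map.geojson")))
  expect_true(file.exists(file.path(out, "manifest.json")))

  results <- utils::read.csv(file.path(out, "results.csv"))
  expect_setequal(unique(results$mode), c("baseline", "carbon"))
  expect_true(all(results$risk >= 1.18 - 1e-9 & results$risk <= 4.25))
  # n.d habitats are present in baseline, absent in carbon mode
  carbon_in <- utils::read.csv(cfg$carbon_table)
  complete <- carbon_in$habitat_label[!is.na(carbon_in$oc_stock_kgCm2) &
                                        !is.na(carbon_in$oc_accumulation_kgCm2yr)]
  labels <- unique(results$habitat_label[results$mode == "baseline"])
  expect_equal(sum(results$mode == "baseline"), 4)
  expect_equal(sum(results$mode == "carbon"), sum(labels %in% complete))
  expect_lt(sum(results$mode == "carbon"), 4)

  risk_map <- read_habitat_map(file.path(out, "risk_map.geojson"))
  props <- risk_map$features[[1]]$properties
  expect_true(all(c("risk_baseline", "risk_carbon") %in% names(props)))
})

test_that("spatial attributes are computed from the map and grid, not the CSV", {
  dir <- withr::local_tempdir()
  cfg <- write_demo_inputs(dir)
  out1 <- file.path(dir, "with_geometry")
  res_geo <- run_assessment(cfg, out = out1)
  cfg_nogeo <- cfg
  cfg_nogeo$habitat_map <- NULL
  cfg_nogeo$sar_grid <- NULL
  res_csv <- run_assessment(cfg_nogeo, out = file.path(dir, "no_geometry"))
  # with geometry the spatial scores vary across habitats; the CSV placeholders
  # are flat, so at least one element must differ between the two routes
  s_geo <- res_geo$results$baseline$spatial
  s_csv <- res_csv$results$baseline$spatial
  expect_false(isTRUE(all.equal(s_geo, s_csv)))
})

test_that("re-running an identical configuration is byte-identical", {
  dir <- withr::local_tempdir()
  cfg <- write_demo_inputs(dir)
  run_assessment(cfg, out = file.path(dir, "a"))
  run_assessment(cfg, out = file.path(dir, "b"))
  for (f in c("results.csv", "comparison.csv", "risk_map.geojson")) {
    expect_identical(unname(tools::md5sum(file.path(dir, "a", f))),
                     unname(tools::md5sum(file.path(dir, "b", f))),
                     label = f)
  }
})

test_that("carbon mode without a carbon table is a configuration error", {
  dir <- withr::local_tempdir()
  cfg <- write_demo_inputs(dir)
  cfg$carbon_table <- NULL
  cfg$mode <- "carbon"
  expect_error(run_assessment(cfg, out = file.path(dir, "out")),
               class = "ccsa_config_error")
})

test_that("failed runs leave no partial outputs behind", {
  dir <- withr::local_tempdir()
  cfg <- write_demo_inputs(dir)
  # poison the carbon table so the carbon leg fails after results.csv is staged
  utils::write.csv(
    data.frame(habitat_label = c("a", "b"), component = "combined",
               oc_stock_kgCm2 = c(-2, 2), oc_accumulation_kgCm2yr = c(0.1, 0.1)),
    cfg$carbon_table, row.names = FALSE)
  out <- file.path(dir, "out")
  expect_error(run_assessment(cfg, out = out), class = "ccsa_validation_error")
  expect_false(file.exists(file.path(out, "results.csv")))
  expect_false(file.exists(file.path(out, "manifest.json")))
})

test_that("the manifest reproduces the run it describes", {
  dir <- withr::local_tempdir()
  cfg <- write_demo_inputs(dir)
  out1 <- file.path(dir, "orig")
  run_assessment(cfg, out = out1)
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg2 <- manifest$config
  cfg2$years <- as.integer(cfg2$years)
  out2 <- file.path(dir, "replay")
  run_assessment(cfg2, out = out2)
  expect_identical(unname(tools::md5sum(file.path(out1, "results.csv"))),
                   unname(tools::md5sum(file.path(out2, "results.csv"))))
})

test_that("mixed-code reclassification relabels, duplicates and validates", {
  map <- structure(list(features = list(
    list(habitat_label = "A5.1/A5.2", zone = "sublittoral",
         polygons = list(square(0, 54, 0.5)), properties = list()),
    list(habitat_label = "Sublittoral sand", zone = "sublittoral",
         polygons = list(square(0.5, 54, 0.5)), properties = list())
  )), class = "ccsa_map")
  reclass <- data.frame(mixed_code = c("A5.1/A5.2", "A5.1/A5.2"),
                        habitat_label = c("Sublittoral coarse sediment",
                                          "Sublittoral sand"))
  out <- reclassify_habitats(map, reclass)
  labs <- vapply(out$features, `[[`, "", "habitat_label")
  expect_equal(sort(labs), sort(c("Sublittoral coarse sediment",
                                  "Sublittoral sand", "Sublittoral sand")))
  # geometry of each duplicate is conserved
  dup <- Filter(function(f) f$habitat_label == "Sublittoral coarse sediment",
                out$features)[[1]]
  expect_equal(geom_area_m2(dup$polygons), geom_area_m2(square(0, 54, 0.5)))

  # a clean map passes through unchanged
  clean <- structure(list(features = map$features[2]), class = "ccsa_map")
  expect_identical(reclassify_habitats(clean, reclass), clean)

  # unmapped mixed codes are named in the error
  bad <- structure(list(features = list(
    list(habitat_label = "A5.3/A5.4", zone = "sublittoral",
         polygons = list(square(0, 54, 0.5)), properties = list()))),
    class = "ccsa_map")
  expect_error(reclassify_habitats(bad, reclass),
               class = "ccsa_validation_error", regexp = "A5.3/A5.4")

  # dissolve merges same-label polygons into one scoring element
  dis <- reclassify_habitats(map, reclass, dissolve = TRUE)
  labs2 <- vapply(dis$features, `[[`, "", "habitat_label")
  expect_equal(anyDuplicated(labs2), 0L)
  sand <- Filter(function(f) f$habitat_label == "Sublittoral sand", dis$features)[[1]]
  expect_length(sand$polygons, 2)
})

test_that("the command-line front-end runs a synthetic assessment", {
  dir <- withr::local_tempdir()
  cfg <- write_demo_inputs(dir)
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cli <- system.file("cli", "ccsa.R", package = "ccsa")
  out <- file.path(dir, "cli_out")
  status <- system2(file.path(R.home("bin"), "Rscript"),
                    c(cli, "assess", "--config", shQuote(cfg_path),
                      "--mode", "both", "--out", shQuote(out)),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "results.csv")),
              info = paste(status, collapse = "\n"))
  # bad configuration exits non-zero
  bad <- suppressWarnings(
    system2(file.path(R.home("bin"), "Rscript"),
            c(cli, "assess", "--config", shQuote(file.path(dir, "missing.yaml"))),
            stdout = NULL, stderr = NULL))
  expect_gt(bad, 0)
})
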