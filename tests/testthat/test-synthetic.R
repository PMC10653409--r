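test_that("the mosaic tessellates the extent without gaps or overlap", {
  sc <- synthetic_scenario(seed = 7, extent = c(-1, 54, 0, 55),
                           n_habitats = 5, n_patches = 20)
  map <- generate_habitat_mosaic(sc)
  total <- sum(vapply(map$features, function(f) geom_area_m2(f$polygons, lat_ts = 54.5),
                      numeric(1)))
  expect_equal(total, rect_area_exact(-1, 54, 0, 55), tolerance = 1e-6)
  expect_setequal(unique(vapply(map$features, `[[`, "", "habitat_label")),
                  sc$habitat_labels)  # every habitat appears
  # pairwise overlap is zero (Voronoi cells are disjoint up to edges)
  f <- map$features
  for (i in seq_len(min(6, length(f)))) {
    for (j in seq_len(i - 1)) {
      ov <- intersection_area_m2(f[[i]]$polygons, f[[j]]$polygons)
      expect_lt(ov / total, 1e-9)
    }
  }
})

test_that("a single-patch scenario yields one polygon covering the extent", {
  sc <- synthetic_scenario(seed = 3, n_habitats = 1, n_patches = 1)
  map <- generate_habitat_mosaic(sc)
  expect_length(map$features, 1)
  expect_equal(geom_area_m2(map$features[[1]]$polygons, lat_ts = 54.5),
               rect_area_exact(-1, 54, 0, 55), tolerance = 1e-9)
})

test_that("mosaic generation is deterministic and validates its parameters", {
  sc <- synthetic_scenario(seed = 11, n_habitats = 4, n_patches = 12)
  m1 <- generate_habitat_mosaic(sc)
  m2 <- generate_habitat_mosaic(sc)
  expect_identical(m1, m2)
  expect_error(synthetic_scenario(seed = 1, n_habitats = 9, n_patches = 4),
               class = "ccsa_parameter_error")
  expect_error(synthetic_scenario(seed = 1, zero_fraction = 1.2),
               class = "ccsa_parameter_error")
})

test_that("SAR field honours the zero-effort fraction and lattice", {
  sc <- synthetic_scenario(seed = 5, extent = c(0, 50, 2.5, 51),
                           zero_fraction = 0.3, autocorr_length = 0)
  grid <- generate_sar_field(sc)
  n <- nrow(grid)
  expect_equal(n, 50 * 20)
  # binomial check: 300 +- 4 sd on 1000 cells
  n_zero <- sum(grid$sar == 0)
  expect_lt(abs(n_zero - 0.3 * n), 4 * sqrt(n * 0.3 * 0.7))
  expect_true(all(grid$sar >= 0))
  # all centres on the 0.05-degree lattice
  expect_true(all(abs((grid$lon / 0.05 - 0.5) -
                        round(grid$lon / 0.05 - 0.5)) < 1e-9))
  expect_true(all(abs((grid$lat / 0.05 - 0.5) -
                        round(grid$lat / 0.05 - 0.5)) < 1e-9))
  all_zero <- generate_sar_field(synthetic_scenario(seed = 5, zero_fraction = 1))
  expect_true(all(all_zero$sar == 0))
  expect_error(generate_sar_field(synthetic_scenario(seed = 5,
                                                     extent = c(0, 50, 1.013, 51))),
               class = "ccsa_parameter_error")
})

test_that("sub-extent generation reproduces the shared cells exactly", {
  big <- synthetic_scenario(seed = 9, extent = c(-1, 54, 1, 55),
                            autocorr_length = 0.1)
  small <- synthetic_scenario(seed = 9, extent = c(-0.5, 54.25, 0.5, 54.75),
                              autocorr_length = 0.1)
  g_big <- generate_sar_field(big)
  g_small <- generate_sar_field(small)
  m <- merge(as.data.frame(g_small), as.data.frame(g_big),
             by = "cell_id", suffixes = c("_small", "_big"))
  expect_equal(nrow(m), nrow(g_small))
  expect_equal(m$sar_small, m$sar_big, tolerance = 1e-12)
})

test_that("smoothing induces positive spatial autocorrelation but keeps the marginal", {
  rough <- generate_sar_field(synthetic_scenario(seed = 13, extent = c(0, 50, 2, 51),
                                                 zero_fraction = 0,
                                                 autocorr_length = 0))
  smooth <- generate_sar_field(synthetic_scenario(seed = 13, extent = c(0, 50, 2, 51),
                                                  zero_fraction = 0,
                                                  autocorr_length = 0.15))
  lag_cor <- function(g) {
    df <- as.data.frame(g)
    df$lon_next <- df$lon + 0.05
    m <- merge(df, df, by.x = c("lon_next", "lat"), by.y = c("lon", "lat"))
    stats::cor(log(m$sar.x), log(m$sar.y))
  }
  expect_lt(abs(lag_cor(rough)), 0.15)
  expect_gt(lag_cor(smooth), 0.5)
  # variance-preserving smoothing: log-sd stays near the configured sdlog
  expect_equal(stats::sd(log(smooth$sar)), 1, tolerance = 0.15)
})

test_that("the packaged case-study fixture carries the published values", {
  fx <- case_study_fixture()
  stock_of <- function(h) fx$carbon$oc_stock[fx$carbon$habitat_label == h]
  accum_of <- function(h) fx$carbon$oc_accumulation[fx$carbon$habitat_label == h]
  expect_equal(stock_of("Littoral mud"), 19.90)
  expect_equal(accum_of("Littoral mud"), 0.084)
  expect_equal(stock_of("Littoral sediments dominated by aquatic angiosperms"), 21.33)
  expect_equal(accum_of("Littoral sediments dominated by aquatic angiosperms"), 0.360)
  expect_true(is.na(stock_of("Biogenic reefs")))
  expect_equal(stock_of("Unknown low carbon capacity habitat"), 0)
  expect_length(fx$elements, 12)
  # non-published attribute values are explicitly flagged
  expect_true(all(c("paper", "placeholder") %in% fx$scores$source))
  placeholder_attrs <- unique(fx$scores$attribute[fx$scores$source == "placeholder"])
  expect_true(all(c("substratum_hardness", "spatial_overlap", "sar") %in%
                    placeholder_attrs))
})

test_that("a max-carbon, max-effort habitat ranks first in carbon mode", {
  sc <- synthetic_scenario(seed = 17, extent = c(0, 54, 1, 55),
                           n_habitats = 4, n_patches = 10,
                           zero_fraction = 0.3)
  map <- generate_habitat_mosaic(sc)
  grid <- generate_sar_field(sc)
  target <- sc$habitat_labels[2]

  # give the target habitat the pool-maximum carbon and saturated effort
  carbon <- data.frame(
    habitat_label = c(sc$habitat_labels, "Unknown low carbon capacity habitat"),
    oc_stock = c(ifelse(sc$habitat_labels == target, 30, 2 + seq_len(4)), 0),
    oc_accumulation = c(ifelse(sc$habitat_labels == target, 0.5, 0.01 * seq_len(4)), 0))
  class(carbon) <- c("ccsa_carbon", "data.frame")
  mx <- max(grid$sar)
  for (f in map$features) {
    if (f$habitat_label == target) {
      w <- ccsa:::cell_weights(f$polygons, grid)
      grid$sar[w > 0] <- mx
    }
  }
  iv <- build_sar_intervals(grid)
  cs <- normalize_carbon(carbon)
  elements <- lapply(seq_along(sc$habitat_labels), function(i) {
    lab <- sc$habitat_labels[i]
    geom <- ccsa:::map_geometry(map, lab)
    el <- scoring_element(i, lab, ccsa:::zone_of_label(lab), scores = c(
      regeneration = 1, natural_disturbance = 1, removability_biota = 3,
      removability_substratum = 3, substratum_hardness = 2,
      substratum_ruggedness = 2, seabed_slope = 2,
      gear_footprint = 3, spatial_overlap = 2))
    el$scores[["sar"]] <- score_sar(geom, grid, iv, dredge)
    el
  })
  res <- assess(elements, default_tables, dredge, mode = "carbon",
                carbon_scores = cs)
  expect_equal(res$habitat_label[which.max(res$risk)], target)
})
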