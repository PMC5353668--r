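small_cfg <- function(seed = 10, ...) {
  synthetic_config(seed = seed, resolution = 12, lat_min = -60, lat_max = 60,
                   taxa = "mammal", ...)
}

test_that("forest history is bounded, monotone, and deterministic", {
  cfg <- small_cfg()
  fh <- generate_forest_history(cfg)
  vals <- unlist(fh$layers)
  expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
  # per-cell non-increasing through time in loss-only mode
  mat <- do.call(cbind, fh$layers)
  diffs <- t(apply(mat, 1, diff))
  expect_true(all(diffs <= 1e-12, na.rm = TRUE))
  # flat across each 50-year reference window
  expect_equal(fh$layers[["1500"]], fh$layers[["1550"]])
  expect_equal(fh$layers[["1950"]], fh$layers[["2000"]])
  # determinism
  fh2 <- generate_forest_history(cfg)
  expect_identical(fh$layers, fh2$layers)
  fh3 <- generate_forest_history(small_cfg(seed = 11))
  expect_false(identical(fh$f1500, fh3$f1500))
})

test_that("zero deforestation leaves the forest unchanged; intensity 1 razes it", {
  fh0 <- generate_forest_history(small_cfg(deforest_intensity = 0))
  expect_equal(fh0$f2000, fh0$f1500)
  fh1 <- generate_forest_history(small_cfg(deforest_intensity = 1,
                                           pressure_gain = 50))
  # cells under saturated pressure approach the floor (0)
  hit <- fh1$loss > 0.99
  expect_true(any(hit, na.rm = TRUE))
  expect_true(all(fh1$f2000[which(hit)] < 0.01 * fh1$f1500[which(hit)]))
})

test_that("direct-SAR richness matches the power law on a known cell", {
  # one wide landless world with a single land cell of area A = 16 km^2
  g <- build_grid(-2, 2, -4, 4, 2, land_mask = c(rep(FALSE, 3),
                                                 TRUE, rep(FALSE, 4)))
  cfg <- synthetic_config(seed = 1, lat_min = -2, lat_max = 2, lon_min = -4,
                          lon_max = 4, resolution = 2, taxa = "mammal",
                          c_true = 10, z_true = 0.25, richness_sigma = 0)
  f <- grid_layer(g, 0)
  land <- which(g$land_mask)
  f[land] <- 16 / g$cell_area[land]
  sp <- generate_species(cfg, f, g)
  r <- rasterize_richness(sp, g)
  expect_equal(unname(r[land]), 20)  # 10 * 16^0.25
})

test_that("species generation is reproducible and demand-exact", {
  cfg <- small_cfg()
  fh <- generate_forest_history(cfg)
  g <- fh$grid
  sp1 <- generate_species(cfg, fh$f1500, g)
  sp2 <- generate_species(cfg, fh$f1500, g)
  expect_identical(sp1$cells, sp2$cells)
  r <- rasterize_richness(sp1, g)
  tg <- attr(sp1, "richness_targets")$mammal
  expect_equal(r, tg)
  expect_error(generate_species(cfg, grid_layer(g, NA_real_), g),
               "all missing")
})

test_that("spreading-dye ranges are connected cell sets on land", {
  cfg <- small_cfg(range_mode = "spreading_dye", n_species = 40)
  fh <- generate_forest_history(cfg)
  g <- fh$grid
  sp <- generate_species(cfg, fh$f1500, g)
  expect_equal(nrow(sp), 40)
  expect_true(all(vapply(sp$cells,
                         function(cc) all(g$land_mask[cc]), TRUE)))
  for (cc in sp$cells[1:15]) expect_true(is_connected(g, cc))
})

test_that("IUCN assignment follows the multinomial probabilities", {
  sp <- toy_species(as.list(rep(1L, 10000)))
  all_dd <- assign_iucn_categories(sp, c(1, 0, 0, 0, 0, 0), seed = 2)
  expect_true(all(all_dd$iucn_category == "DD"))
  probs <- c(0.1, 0.4, 0.1, 0.2, 0.1, 0.1)
  draw <- assign_iucn_categories(sp, probs, seed = 3)
  freq_dd <- mean(draw$iucn_category == "DD")
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(freq_dd - 0.1), 3 * se)
  draw2 <- assign_iucn_categories(sp, probs, seed = 3)
  expect_identical(draw$iucn_category, draw2$iucn_category)
  expect_error(assign_iucn_categories(sp, c(0.5, 0.5, 0.5, 0, 0, 0), 1),
               "sum to 1")
  expect_error(assign_iucn_categories(sp, c(-0.1, 1.1, 0, 0, 0, 0), 1),
               "non-negative")
})

test_that("whole worlds regenerate identically from (config, seed)", {
  cfg <- small_cfg()
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$richness, w2$richness)
  expect_identical(w1$species$iucn_category, w2$species$iucn_category)
  expect_identical(w1$truth, w2$truth)
})
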