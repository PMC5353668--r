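test_that("epoch means average annual layers cellwise", {
  g <- toy_grid()
  const <- grid_layer(g, 0.4)
  expect_equal(epoch_mean(list(const, const, const)), const)
  ramp <- lapply(seq(0, 1, length.out = 11), function(v) grid_layer(g, v))
  expect_equal(epoch_mean(ramp), grid_layer(g, 0.5))
  expect_equal(epoch_mean(ramp[3]), ramp[[3]])
  expect_error(epoch_mean(list(const, grid_layer(build_grid(resolution = 10)))),
               "same grid")
})

test_that("forest area scales cell area by the cover fraction", {
  g <- build_grid(resolution = 1)
  eq_cell <- which(g$centroid_lat == 0.5 & g$centroid_lon == 0.5)
  f <- grid_layer(g, 0.5)
  a <- forest_area(g, f)
  expect_equal(a[eq_cell], 0.5 * cell_area(0, 1, 1))
  expect_lt(abs(a[eq_cell] - 6.18e3), 10)
  expect_equal(forest_area(g, grid_layer(g, 0))[eq_cell], 0)
  expect_equal(forest_area(g, grid_layer(g, 1))[eq_cell], g$cell_area[eq_cell])
  expect_error(forest_area(g, grid_layer(g, 1.2)), "\\[0, 1\\]")
})

test_that("connectivity matches its definition, is linear, agrees with brute force", {
  # two-cell world via a manual distance matrix
  g2 <- build_grid(0, 10, 0, 20, 10, land_mask = c(TRUE, TRUE))
  d <- manual_distances(matrix(c(0, 500, 500, 0), 2), c(1L, 2L))
  areas <- c(100, 40)
  ifm <- connectivity_ifm(g2, areas, d, alpha = 0.002)
  expect_equal(ifm[1], 40 * exp(-0.002 * 500))
  expect_equal(ifm[2], 100 * exp(-0.002 * 500))
  expect_equal(connectivity_ifm(g2, 2 * areas, d, alpha = 0.002), 2 * ifm)
  expect_lt(max(connectivity_ifm(g2, areas, d, alpha = 100)), 1e-40)
  expect_error(connectivity_ifm(g2, areas, d, alpha = 0), "alpha")

  set.seed(11)
  mask <- runif(48) > 0.25
  g <- toy_grid(land_mask = mask)
  a <- grid_layer(g, runif(g$ncell, 0, 1000))
  dm <- distance_matrix(g)
  got <- connectivity_ifm(g, a, dm, alpha = 0.001)
  want <- brute_ifm(g, a, 0.001)
  expect_equal(got[mask], want[mask], tolerance = 1e-12)
})

test_that("proximity matches its definition, radius rule and brute force", {
  g2 <- build_grid(0, 10, 0, 20, 10, land_mask = c(TRUE, TRUE))
  d <- manual_distances(matrix(c(0, 500, 500, 0), 2), c(1L, 2L))
  prox <- proximity(g2, c(100, 40), d)
  expect_equal(prox[1], 40 / 500^2)
  expect_equal(prox[2], 100 / 500^2)
  # radius below the minimum separation: all zero
  expect_equal(unname(proximity(g2, c(100, 40), d, h = 100)[1:2]), c(0, 0))
  # inverse-square homogeneity: doubling distances divides by 4
  d2 <- manual_distances(2 * matrix(c(0, 500, 500, 0), 2), c(1L, 2L))
  expect_equal(proximity(g2, c(100, 40), d2), prox / 4)

  set.seed(12)
  mask <- runif(48) > 0.25
  g <- toy_grid(land_mask = mask)
  a <- grid_layer(g, runif(g$ncell, 0, 1000))
  dm <- distance_matrix(g)
  expect_equal(proximity(g, a, dm)[mask], brute_prox(g, a)[mask],
               tolerance = 1e-12)
  expect_equal(proximity(g, a, dm, h = 2000)[mask],
               brute_prox(g, a, h = 2000)[mask], tolerance = 1e-12)
})

test_that("concentration sums the focal cell and its von Neumann neighbors", {
  g <- build_grid(resolution = 10)        # wrapping global grid
  a <- grid_layer(g, 7)
  conc <- concentration(g, a)
  interior <- (9 - 1) * 36 + 5
  expect_equal(conc[interior], 5 * 7)
  expect_equal(conc[3], 4 * 7)            # polar row: 3 neighbors + self
  # single nonzero cell spreads to its neighbors only
  a1 <- grid_layer(g, 0); a1[interior] <- 11
  c1 <- concentration(g, a1)
  expect_equal(c1[interior], 11)
  expect_equal(unname(c1[cell_neighbors(g, interior)]), rep(11, 4))
  expect_equal(sum(c1 > 0), 5)
  # identity: conc - area = neighbor sum; masked neighbors contribute zero
  set.seed(13)
  mask <- runif(g$ncell) > 0.3
  gm <- build_grid(resolution = 10, land_mask = mask)
  am <- grid_layer(gm, runif(gm$ncell, 0, 10))
  cm <- concentration(gm, am)
  i <- which(mask)[10]
  nb <- cell_neighbors(gm, i)
  expect_equal(cm[i] - am[i],
               sum(ifelse(is.na(am[nb]), 0, am[nb])))
})

test_that("all metrics are non-negative and linear in the area field", {
  set.seed(14)
  g <- toy_grid()
  a <- grid_layer(g, runif(g$ncell, 0, 500))
  dm <- distance_matrix(g)
  for (f in list(function(a) connectivity_ifm(g, a, dm),
                 function(a) proximity(g, a, dm),
                 function(a) concentration(g, a))) {
    v <- f(a)
    expect_true(all(v >= 0, na.rm = TRUE))
    expect_equal(f(3 * a), 3 * v, tolerance = 1e-12)
  }
})

test_that("the metric set emits eight predictors on land cells", {
  set.seed(15)
  mask <- runif(48) > 0.2
  g <- toy_grid(land_mask = mask)
  f1 <- grid_layer(g, runif(g$ncell, 0.2, 0.9))
  f2 <- pmin(f1, grid_layer(g, runif(g$ncell, 0.1, 0.8)))
  m <- forest_metric_set(g, f1, f2)
  expect_equal(nrow(m), sum(mask))
  expect_setequal(setdiff(names(m), "cell_id"),
                  c("Areas1500", "Areas2000", "IFM1500", "IFM2000",
                    "Prox1500", "Prox2000", "Conc1500", "Conc2000"))
  expect_true(all(m$Conc1500 >= m$Areas1500))
  expect_true(all(as.matrix(m[-1]) >= 0))
})
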