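test_that("pearson test recovers exact and null correlations", {
  x <- c(1, 2, 4, 8, 9, 12)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -2 * x + 3)$r, -1)
  # paired antisymmetric design: zero correlation by construction
  x0 <- c(-2, -1, 1, 2)
  y0 <- c(1, -1, -1, 1)
  expect_equal(pearson_cor(x0, y0)$r, 0)
  expect_error(pearson_cor(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")
})

test_that("effective sample size is near n for independent data", {
  set.seed(21)
  n <- 500
  lat <- runif(n, -60, 60); lon <- runif(n, -180, 180)
  pairs <- forestdebt:::crh_pairs(lat, lon, 13)
  ess <- replicate(200, modified_ttest(rnorm(n), rnorm(n), lat, lon,
                                       pairs = pairs)$ess)
  expect_lt(abs(mean(ess) - n) / n, 0.10)
})

test_that("shared spatial autocorrelation deflates the effective sample size", {
  set.seed(22)
  g <- build_grid(-50, 50, -180, 180, 10)
  lat <- g$centroid_lat; lon <- g$centroid_lon
  x <- forestdebt:::gaussian_random_field(g, 4) + 0.1 * rnorm(g$ncell)
  y <- forestdebt:::gaussian_random_field(g, 4) + 0.1 * rnorm(g$ncell)
  m <- modified_ttest(x, y, lat, lon)
  expect_lt(m$ess, g$ncell / 4)
  expect_gt(m$p, pearson_cor(x, y)$p)
  expect_error(modified_ttest(rep(1, g$ncell), y, lat, lon), "zero variance")
})

test_that("semi-partial correlation reduces to Pearson without active controls", {
  set.seed(23)
  n <- 60
  x <- rnorm(n); y <- x + rnorm(n)
  expect_equal(semipartial_cor(y, x)$r, pearson_cor(y, x)$r, tolerance = 1e-12)
  # controls exactly orthogonal to x leave the residual equal to centered x
  q <- orthonormal_design(n, 3, seed = 23)
  expect_equal(semipartial_cor(y, q[, 1], q[, 2:3])$r,
               pearson_cor(y, q[, 1])$r, tolerance = 1e-10)
  expect_equal(semipartial_cor(y, x)$df, n - 2)
  q2 <- orthonormal_design(n, 3, seed = 99)
  expect_equal(semipartial_cor(y, x, q2)$df, n - 3 - 2)
  Z <- cbind(x, rnorm(n))
  expect_error(semipartial_cor(y, 2 * x + 1, Z), "span")
})

test_that("partial correlation matches the three-variable closed form", {
  # construct exact pairwise correlations of 0.5 from an orthonormal basis
  n <- 40
  q <- orthonormal_design(n, 3, seed = 24)
  r <- 0.5
  make <- function(e) r * q[, 1] + sqrt(1 - r^2) * e
  x <- q[, 1]
  # r_yz = r^2 + (1-r^2) * cor(e_y, e_z); choose correlated noise to hit 0.5
  target <- (0.5 - r^2) / (1 - r^2)
  e_y <- q[, 2]
  e_z <- target * q[, 2] + sqrt(1 - target^2) * q[, 3]
  y <- make(e_y); z <- make(e_z)
  expect_equal(cor(x, y), 0.5, tolerance = 1e-12)
  expect_equal(cor(x, z), 0.5, tolerance = 1e-12)
  expect_equal(cor(y, z), 0.5, tolerance = 1e-12)
  expect_equal(partial_cor(y, x, z)$r, 1 / 3, tolerance = 1e-10)

  set.seed(25)
  a <- rnorm(50); b <- 0.5 * a + rnorm(50); c <- 0.3 * a + 0.4 * b + rnorm(50)
  rab <- cor(a, b); rac <- cor(a, c); rbc <- cor(b, c)
  closed <- (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  expect_equal(partial_cor(a, b, c)$r, closed, tolerance = 1e-10)
  expect_equal(partial_cor(a, b, NULL)$r, pearson_cor(a, b)$r, tolerance = 1e-12)
  expect_error(partial_cor(c, a, cbind(c, b)), "span")
})

test_that("Bonferroni adjustment multiplies, caps, and stays monotone", {
  expect_equal(bonferroni(0.01, 8), 0.08)
  expect_equal(bonferroni(0.2, 8), 1)
  expect_equal(bonferroni(c(0.1, 0.5), 1), c(0.1, 0.5))
  p <- sort(runif(20))
  expect_true(all(diff(bonferroni(p, 8)) >= 0))
  expect_error(bonferroni(0.5, 0), "family size")
  expect_error(bonferroni(1.5, 2), "\\[0, 1\\]")
})

test_that("randomization test gives exact extremes and uniform null p-values", {
  x <- rnorm(200)
  r <- randomization_test(x, x, B = 99, seed = 5)
  expect_equal(r$p, 1 / 100)
  expect_equal(randomization_test(x, x, B = 99, seed = 5)$p, r$p)
  # independent x, y: permutation p-values approximately uniform
  set.seed(26)
  ps <- replicate(200, {
    randomization_test(rnorm(40), rnorm(40), B = 199)$p
  })
  d <- suppressWarnings(ks.test(ps, "punif"))$statistic
  expect_lt(unname(d), 0.12)
  expect_error(randomization_test(rep(1, 10), rnorm(10)), "zero variance")
})
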