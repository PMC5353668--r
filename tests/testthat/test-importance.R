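
test_that("subset R-squared map matches direct least-squares fits", {
  set.seed(31)
  n <- 50
  X <- matrix(rnorm(n * 3), n, 3)
  y <- X %*% c(1, 0.5, -0.2) + rnorm(n)
  r2 <- forestdebt:::r2_subsets(X, y)
  expect_equal(r2[1], 0)
  expect_equal(r2[2], as.numeric(cor(y, X[, 1]))^2, tolerance = 1e-12)
  expect_equal(r2[8], summary(lm(y ~ X))$r.squared, tolerance = 1e-12)
  expect_error(forestdebt:::r2_subsets(cbind(X, X[, 1]), y), "rank deficient")
})

test_that("lmg equals the brute-force average over all orderings", {
  set.seed(32)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4)
  X[, 2] <- X[, 1] * 0.7 + X[, 2]       # correlated design
  y <- X %*% c(1, -0.5, 0.3, 0) + rnorm(n)
  got <- unname(lmg(X, y))
  expect_equal(got, brute_lmg(X, y), tolerance = 1e-12)
  expect_equal(sum(got), summary(lm(y ~ X))$r.squared, tolerance = 1e-10)
  # single predictor: lmg is the full R^2
  x1 <- X[, 1, drop = FALSE]
  expect_equal(unname(lmg(x1, y)), summary(lm(y ~ x1))$r.squared,
               tolerance = 1e-12)
})

test_that("orthogonal designs collapse all four metrics to squared correlations", {
  n <- 80
  X <- orthonormal_design(n, 4, seed = 33)
  set.seed(133)
  y <- X %*% c(0.8, -0.6, 0.4, 0.2) + rnorm(n)
  want <- as.numeric(cor(X, y))^2
  expect_equal(unname(lmg(X, y)), want, tolerance = 1e-10)
  expect_equal(unname(first_importance(X, y)), want, tolerance = 1e-10)
  expect_equal(unname(last_importance(X, y)), want, tolerance = 1e-10)
  expect_equal(unname(genizi(X, y)), want, tolerance = 1e-10)
  expect_equal(sum(first_importance(X, y)), summary(lm(y ~ X))$r.squared,
               tolerance = 1e-10)
})

test_that("genizi matches a closed-form 2x2 square-root oracle and sums to R^2", {
  set.seed(34)
  n <- 70
  x1 <- rnorm(n); x2 <- 0.6 * x1 + rnorm(n)
  X <- cbind(x1, x2)
  y <- x1 - 0.5 * x2 + rnorm(n)
  r <- cor(x1, x2)
  # closed-form symmetric square root of [[1, r], [r, 1]]
  a <- (sqrt(1 + r) + sqrt(1 - r)) / 2
  b <- (sqrt(1 + r) - sqrt(1 - r)) / 2
  beta <- solve(matrix(c(1, r, r, 1), 2), as.numeric(cor(X, y)))
  oracle <- c((a * beta[1] + b * beta[2])^2, (b * beta[1] + a * beta[2])^2)
  expect_equal(unname(genizi(X, y)), oracle, tolerance = 1e-10)

  set.seed(35)
  X8 <- matrix(rnorm(100 * 6), 100, 6) %*%
    chol(0.4 + 0.6 * diag(6))            # correlated predictors
  y8 <- X8 %*% rnorm(6) + rnorm(100)
  full <- summary(lm(y8 ~ X8))$r.squared
  expect_equal(sum(genizi(X8, y8)), full, tolerance = 1e-10)
  expect_equal(sum(lmg(X8, y8)), full, tolerance = 1e-10)
  expect_true(all(genizi(X8, y8) >= 0))
  expect_true(all(lmg(X8, y8) >= 0))
})

test_that("metrics are invariant to affine rescaling of predictors", {
  set.seed(36)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  y <- X %*% c(1, 2, -1) + rnorm(n)
  X2 <- X
  X2[, 2] <- 3.7 * X[, 2] - 11
  for (f in list(lmg, first_importance, last_importance, genizi)) {
    expect_equal(unname(f(X, y)), unname(f(X2, y)), tolerance = 1e-10)
  }
})

test_that("degenerate designs error: duplicated predictor, single predictor last", {
  set.seed(37)
  x <- rnorm(30); y <- x + rnorm(30)
  expect_error(last_importance(cbind(x, x), y), "rank deficient")
  expect_equal(unname(last_importance(cbind(x), y)),
               summary(lm(y ~ x))$r.squared, tolerance = 1e-12)
})

test_that("bootstrap importance is reproducible and brackets the point estimate", {
  set.seed(38)
  n <- 120
  X <- matrix(rnorm(n * 3), n, 3)
  colnames(X) <- c("a", "b", "c")
  y <- X %*% c(1, 0.5, 0) + rnorm(n)
  b1 <- bootstrap_importance(X, y, B = 1, seed = 7)
  b1b <- bootstrap_importance(X, y, B = 1, seed = 7)
  expect_equal(b1$ci_low, b1b$ci_low)
  res <- bootstrap_importance(X, y, B = 200, seed = 8)
  expect_true(all(res$point >= res$ci_low - 1e-12))
  expect_true(all(res$point <= res$ci_high + 1e-12))
  expect_equal(res$skipped, 0L)
  td <- tidy_importance(res)
  expect_equal(nrow(td), 4 * 3)
  expect_equal(td$value[td$metric == "lmg" & td$predictor == "a"],
               unname(res$point["lmg", "a"]))
})
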