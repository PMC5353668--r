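# Decomposition of linear-model R^2 across predictors: lmg (Shapley-type
# average over orderings), first, last, and the genizi decomposition, with
# case-resampling bootstrap intervals.

# R^2 of the OLS fit (with intercept) of y on each subset of predictor
# columns, from the joint covariance matrix. Returned as a vector indexed by
# subset bitmask + 1; the empty subset has R^2 = 0.
r2_subsets <- function(X, y) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p > 15) stop("subset enumeration limited to 15 predictors")
  if (qr(cbind(1, X))$rank < p + 1) stop("full predictor matrix is rank deficient")
  if (stats::var(y) == 0) stop("response has zero variance")
  # solve on the correlation scale: R^2 is scale-invariant and the predictor
  # columns (areas, connectivity, proximity) span many orders of magnitude
  C <- stats::cor(cbind(y, X))
  sxy <- C[-1, 1, drop = FALSE]
  sxx <- C[-1, -1, drop = FALSE]
  syy <- 1
  out <- numeric(2^p)
  for (mask in seq_len(2^p - 1)) {
    s <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) > 0)
    b <- solve(sxx[s, s, drop = FALSE], sxy[s, , drop = FALSE])
    out[mask + 1] <- drop(crossprod(sxy[s, , drop = FALSE], b)) / syy
  }
  out
}

# lmg/first/last share one subset map; the lattice bookkeeping (which masks
# exclude each predictor, subset sizes, ordering weights) depends only on p
# and is cached across calls.
lmg_lattice <- local({
  cache <- list()
  function(p) {
    key <- as.character(p)
    if (!is.null(cache[[key]])) return(cache[[key]])
    masks <- 0:(2^p - 1)
    size <- integer(2^p)
    for (b in 0:(p - 1)) size <- size + (bitwAnd(masks, bitwShiftL(1L, b)) > 0)
    wt <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - (0:(p - 1))) -
                lfactorial(p))
    without <- lapply(seq_len(p), function(k)
      masks[bitwAnd(masks, bitwShiftL(1L, k - 1L)) == 0])
    out <- list(size = size, wt = wt, without = without)
    cache[[key]] <<- out
    out
  }
})

importance_from_r2 <- function(r2, p, metrics) {
  lat <- lmg_lattice(p)
  out <- list()
  if ("lmg" %in% metrics) {
    out$lmg <- vapply(seq_len(p), function(k) {
      m0 <- lat$without[[k]]
      m1 <- m0 + bitwShiftL(1L, k - 1L)
      sum(lat$wt[lat$size[m0 + 1] + 1] * (r2[m1 + 1] - r2[m0 + 1]))
    }, 0)
  }
  if ("first" %in% metrics)
    out$first <- r2[bitwShiftL(1L, seq_len(p) - 1L) + 1]
  if ("last" %in% metrics) {
    full <- 2^p - 1
    out$last <- vapply(seq_len(p), function(k)
      r2[full + 1] - r2[full - bitwShiftL(1L, k - 1L) + 1], 0)
  }
  out
}

importance_point <- function(X, y, metrics) {
  X <- as.matrix(X)
  p <- ncol(X)
  need_r2 <- any(c("lmg", "first", "last") %in% metrics)
  vals <- if (need_r2) importance_from_r2(r2_subsets(X, y), p, metrics) else list()
  if ("genizi" %in% metrics) vals$genizi <- unname(genizi(X, y))
  mat <- do.call(rbind, vals[metrics])
  colnames(mat) <- colnames(X)
  mat
}

#' LMG relative importance
#'
#' The average, over all `p!` orderings of model entry, of the incremental
#' R^2 contributed by each predictor when it enters — a Shapley-value
#' decomposition of the full-model R^2, computed with the standard
#' combinatorial weights `|S|! (p - |S| - 1)! / p!` over the subset lattice.
#'
#' @param X Predictor matrix or data frame.
#' @param y Response vector.
#' @return Named numeric vector of per-predictor contributions; sums to the
#'   full-model R^2.
#' @export
lmg <- function(X, y) {
  X <- as.matrix(X)
  v <- importance_from_r2(r2_subsets(X, y), ncol(X), "lmg")$lmg
  stats::setNames(v, colnames(X))
}

#' "First" relative importance
#'
#' Each predictor's R^2 when entered alone: the squared Pearson correlation
#' with the response.
#'
#' @inheritParams lmg
#' @return Named numeric vector.
#' @export
first_importance <- function(X, y) {
  X <- as.matrix(X)
  v <- importance_from_r2(r2_subsets(X, y), ncol(X), "first")$first
  stats::setNames(v, colnames(X))
}

#' "Last" relative importance
#'
#' Each predictor's increment to R^2 when entered last:
#' `R2(full) - R2(full minus k)`.
#'
#' @inheritParams lmg
#' @return Named numeric vector.
#' @export
last_importance <- function(X, y) {
  X <- as.matrix(X)
  v <- importance_from_r2(r2_subsets(X, y), ncol(X), "last")$last
  stats::setNames(v, colnames(X))
}

#' Genizi R^2 decomposition
#'
#' With standardized predictors, correlation matrix `Rxx` and standardized
#' coefficients `beta`, assigns predictor `k` the value
#' `sum_j ((Rxx^(1/2))_kj * beta_j)^2`, using the symmetric positive-definite
#' matrix square root. The values are non-negative and sum to the full-model
#' R^2.
#'
#' @inheritParams lmg
#' @return Named numeric vector.
#' @export
genizi <- function(X, y) {
  X <- as.matrix(X)
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("predictor matrix is rank deficient")
  Rxx <- stats::cor(X)
  e <- eigen(Rxx, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("predictor correlation matrix is not positive definite")
  root <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
  rxy <- stats::cor(X, y)
  beta <- solve(Rxx, rxy)
  stats::setNames(as.numeric((root %*% beta)^2), colnames(X))
}

#' Bootstrap relative-importance analysis
#'
#' Computes lmg, first, last and genizi together with case-resampling
#' bootstrap percentile intervals. Bootstrap replicates whose resampled
#' design is rank deficient (or has a non-positive-definite predictor
#' correlation) are skipped and counted.
#'
#' @param X Predictor matrix or data frame.
#' @param y Response vector.
#' @param B Bootstrap iterations (default 10000).
#' @param seed Optional integer seed.
#' @param level Confidence level for percentile intervals (default 0.95).
#' @param metrics Which metrics to compute.
#' @return An `importance_result`: point estimates (matrix metric x
#'   predictor), `ci_low`/`ci_high` matrices, full-model `r_squared`, `B`,
#'   number of `skipped` replicates, and `seed`.
#' @export
bootstrap_importance <- function(X, y, B = 10000, seed = NULL, level = 0.95,
                                 metrics = c("lmg", "first", "last", "genizi")) {
  if (B < 1) stop("B must be at least 1")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  metrics <- match.arg(metrics, several.ok = TRUE)
  point <- importance_point(X, y, metrics)
  n <- length(y)
  if (!is.null(seed)) set.seed(seed)
  draws <- array(NA_real_, c(B, length(metrics), ncol(X)))
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, replace = TRUE)
    rep_vals <- tryCatch(
      importance_point(X[idx, , drop = FALSE], y[idx], metrics),
      error = function(e) NULL)
    if (is.null(rep_vals)) skipped <- skipped + 1L else draws[b, , ] <- rep_vals
  }
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci_low <- apply(draws, c(2, 3), stats::quantile, probs = qs[1], na.rm = TRUE)
  ci_high <- apply(draws, c(2, 3), stats::quantile, probs = qs[2], na.rm = TRUE)
  dimnames(ci_low) <- dimnames(ci_high) <- dimnames(point)
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high,
                 r_squared = r2_subsets(X, y)[2^ncol(X)],
                 B = B, skipped = skipped, seed = seed, level = level),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("relative importance (R^2 = %.4f, B = %d bootstrap, %d skipped)\n",
              x$r_squared, x$B, x$skipped))
  print(round(x$point, 4))
  invisible(x)
}

#' Tidy an importance result into a long table
#'
#' @param x An `importance_result`.
#' @return Data frame with columns `predictor`, `metric`, `value`, `ci_low`,
#'   `ci_high`.
#' @export
tidy_importance <- function(x) {
  stopifnot(inherits(x, "importance_result"))
  g <- expand.grid(metric = rownames(x$point), predictor = colnames(x$point),
                   stringsAsFactors = FALSE)
  data.frame(predictor = g$predictor, metric = g$metric,
             value = x$point[cbind(g$metric, g$predictor)],
             ci_low = x$ci_low[cbind(g$metric, g$predictor)],
             ci_high = x$ci_high[cbind(g$metric, g$predictor)])
}
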