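# Forest fragmentation predictors per epoch: area, incidence-function
# connectivity, proximity, and von Neumann concentration.

#' Mean forest fraction over an epoch window
#'
#' Epoch layers (e.g. the 1500s and 2000s) are taken as the per-cell mean of
#' annual forest-fraction layers over a 50-year window.
#'
#' @param annual_layers List of layer vectors on a common grid.
#' @return Per-cell mean layer.
#' @export
epoch_mean <- function(annual_layers) {
  stopifnot(length(annual_layers) >= 1)
  n <- unique(lengths(annual_layers))
  if (length(n) != 1) stop("annual layers are not on the same grid")
  Reduce(`+`, annual_layers) / length(annual_layers)
}

#' Per-cell forest area
#'
#' Multiplies the forest-cover fraction by the spherical cell area.
#'
#' @param grid A `grid_spec`.
#' @param fraction Forest-fraction layer in `[0, 1]`.
#' @return Per-cell forest area in km^2 (`NA` off land).
#' @export
forest_area <- function(grid, fraction) {
  stopifnot(length(fraction) == grid$ncell)
  ok <- is.na(fraction) | (fraction >= 0 & fraction <= 1)
  if (!all(ok)) stop("forest fractions must lie in [0, 1]")
  out <- fraction * grid$cell_area
  out[!grid$land_mask] <- NA_real_
  out
}

#' Incidence-function connectivity (IFM)
#'
#' Distance-decayed sum of surrounding forest areas,
#' `IFM(i) = sum_{j != i} exp(-alpha * d_ij) * A(j)`, from metapopulation
#' theory; it indexes the colonization potential a cell offers. The focal
#' cell is excluded; entries flagged absent in the distance matrix (beyond
#' its cutoff) contribute zero.
#'
#' @param grid A `grid_spec`.
#' @param areas Per-cell forest area (km^2).
#' @param distances Matrix from [distance_matrix()].
#' @param alpha Exponential decay rate in 1/km (default 0.001, an e-folding
#'   distance of 1000 km).
#' @return Per-cell IFM layer (`NA` off land).
#' @export
connectivity_ifm <- function(grid, areas, distances, alpha = 0.001) {
  if (alpha <= 0) stop("alpha must be positive")
  ids <- attr(distances, "cell_ids")
  a <- areas[ids]
  k <- exp(-alpha * distances)
  k[is.na(k)] <- 0
  diag(k) <- 0
  a0 <- ifelse(is.na(a), 0, a)
  out <- grid_layer(grid)
  out[ids] <- as.numeric(k %*% a0)
  out
}

#' Forest proximity index
#'
#' Inverse-square-distance-weighted sum of surrounding forest areas,
#' `Prox(i) = sum_{j != i, d_ij <= h} A(j) / d_ij^2`. Low values indicate
#' fragmented, spatially disjunct forest.
#'
#' @param grid A `grid_spec`.
#' @param areas Per-cell forest area (km^2).
#' @param distances Matrix from [distance_matrix()].
#' @param h Optional search radius in km (default `NULL` = no limit).
#' @return Per-cell proximity layer (`NA` off land).
#' @export
proximity <- function(grid, areas, distances, h = NULL) {
  if (!is.null(h) && h <= 0) stop("search radius must be positive")
  ids <- attr(distances, "cell_ids")
  a <- areas[ids]
  w <- 1 / distances^2
  w[is.na(w)] <- 0
  diag(w) <- 0
  if (!is.null(h)) w[distances > h] <- 0
  a0 <- ifelse(is.na(a), 0, a)
  out <- grid_layer(grid)
  out[ids] <- as.numeric(w %*% a0)
  out
}

#' Forest concentration index
#'
#' Total forest in a focal cell plus its four von Neumann neighbors:
#' `Conc(i) = sum_{j in S(i)} A(j)` with `S(i) = {i} + neighbors`. Masked or
#' missing neighbors contribute zero; polar-row cells have three neighbors.
#'
#' @param grid A `grid_spec`.
#' @param areas Per-cell forest area (km^2).
#' @return Per-cell concentration layer (`NA` off land).
#' @export
concentration <- function(grid, areas) {
  stopifnot(length(areas) == grid$ncell)
  a0 <- ifelse(is.na(areas), 0, areas)
  out <- grid_layer(grid)
  for (i in which(grid$land_mask)) {
    out[i] <- a0[i] + sum(a0[cell_neighbors(grid, i)])
  }
  out
}

#' Compute the eight forest predictors for two epochs
#'
#' Convenience wrapper assembling `Areas`, `IFM`, `Prox` and `Conc` for the
#' past (1500s) and current (2000s) epoch layers into one table.
#'
#' @param grid A `grid_spec`.
#' @param fraction_1500,fraction_2000 Epoch-mean forest-fraction layers.
#' @param alpha IFM decay rate (1/km).
#' @param h Proximity search radius (km) or `NULL`.
#' @param cutoff Connectivity distance cutoff (km) or `NULL`.
#' @return A data frame with one row per land cell: `cell_id` plus columns
#'   `Areas1500`, `Areas2000`, `IFM1500`, `IFM2000`, `Prox1500`, `Prox2000`,
#'   `Conc1500`, `Conc2000`.
#' @export
forest_metric_set <- function(grid, fraction_1500, fraction_2000,
                              alpha = 0.001, h = NULL, cutoff = NULL) {
  d <- distance_matrix(grid, cutoff = cutoff)
  ids <- attr(d, "cell_ids")
  one <- function(fraction) {
    a <- forest_area(grid, fraction)
    list(areas = a,
         ifm = connectivity_ifm(grid, a, d, alpha = alpha),
         prox = proximity(grid, a, d, h = h),
         conc = concentration(grid, a))
  }
  p <- one(fraction_1500); q <- one(fraction_2000)
  data.frame(cell_id = ids,
             Areas1500 = p$areas[ids], Areas2000 = q$areas[ids],
             IFM1500 = p$ifm[ids], IFM2000 = q$ifm[ids],
             Prox1500 = p$prox[ids], Prox2000 = q$prox[ids],
             Conc1500 = p$conc[ids], Conc2000 = q$conc[ids])
}
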