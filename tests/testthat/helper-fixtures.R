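# Shared fixtures: tiny grids, toy species tables, brute-force oracles.

R_EARTH <- 6371.0088

# small all-land grid (default 8 x 6 cells of 10 degrees over a band)
toy_grid <- function(resolution = 10, lat_min = -30, lat_max = 30,
                     lon_min = -40, lon_max = 40, land_mask = NULL) {
  build_grid(lat_min, lat_max, lon_min, lon_max, resolution, land_mask)
}

toy_species <- function(cells, taxon = "mammal", category = "LC",
                        habitat = list(c("forest", "terrestrial"))) {
  n <- length(cells)
  species_table(sprintf("sp%03d", seq_len(n)),
                rep_len(taxon, n),
                rep_len(habitat, n),
                rep_len(category, n),
                cells)
}

# independent O(n^2) oracles for the metric kernels
brute_ifm <- function(grid, areas, alpha) {
  ids <- which(grid$land_mask)
  out <- rep(NA_real_, grid$ncell)
  for (i in ids) {
    acc <- 0
    for (j in ids) {
      if (i == j) next
      d <- great_circle_distance(grid$centroid_lat[i], grid$centroid_lon[i],
                                 grid$centroid_lat[j], grid$centroid_lon[j])
      acc <- acc + exp(-alpha * d) * areas[j]
    }
    out[i] <- acc
  }
  out
}

brute_prox <- function(grid, areas, h = NULL) {
  ids <- which(grid$land_mask)
  out <- rep(NA_real_, grid$ncell)
  for (i in ids) {
    acc <- 0
    for (j in ids) {
      if (i == j) next
      d <- great_circle_distance(grid$centroid_lat[i], grid$centroid_lon[i],
                                 grid$centroid_lat[j], grid$centroid_lon[j])
      if (!is.null(h) && d > h) next
      acc <- acc + areas[j] / d^2
    }
    out[i] <- acc
  }
  out
}

# distance matrix with prescribed entries, for kernel unit tests
manual_distances <- function(d, cell_ids) {
  attr(d, "cell_ids") <- cell_ids
  d
}

# columns with exactly zero pairwise sample correlation, unit variance
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n))))[, -1, drop = FALSE]
  scale(q, center = TRUE, scale = TRUE)
}

# is a cell set connected under von Neumann adjacency?
is_connected <- function(grid, cells) {
  if (length(cells) <= 1) return(TRUE)
  seen <- cells[1]
  frontier <- cells[1]
  while (length(frontier)) {
    nb <- unique(unlist(lapply(frontier, cell_neighbors, grid = grid)))
    frontier <- setdiff(intersect(nb, cells), seen)
    seen <- c(seen, frontier)
  }
  length(seen) == length(cells)
}

# brute-force average of incremental R^2 over all p! orderings, R^2 via lm()
brute_lmg <- function(X, y) {
  p <- ncol(X)
  perms <- as.matrix(expand.grid(rep(list(seq_len(p)), p)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == p), ,
                 drop = FALSE]
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  out <- numeric(p)
  for (i in seq_len(nrow(perms))) {
    ord <- perms[i, ]
    for (k in seq_len(p)) {
      before <- if (k == 1) integer(0) else ord[1:(k - 1)]
      out[ord[k]] <- out[ord[k]] + r2(c(before, ord[k])) - r2(before)
    }
  }
  out / nrow(perms)
}
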