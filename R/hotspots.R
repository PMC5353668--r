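# IUCN-probability extinction-risk maps, top-decile hotspot extraction and
# the conservation-gap (spatial mismatch) report.

#' Category-to-probability table for extinction risk
#'
#' Numeric extinction probabilities assigned to the IUCN Red List
#' categories: DD 0.0001, LC 0.001, NT 0.01, VU 0.1, EN 0.667, CR 0.999.
#'
#' @return Named numeric vector.
#' @export
iucn_extinction_probs <- function() {
  c(DD = 0.0001, LC = 0.001, NT = 0.01, VU = 0.1, EN = 0.667, CR = 0.999)
}

#' Per-cell summed extinction risk
#'
#' For each cell, the sum over species occurring there of the extinction
#' probability assigned to the species' IUCN category.
#'
#' @param species A species table (EX/EW should be excluded upstream; they
#'   carry no probability).
#' @param grid A `grid_spec`.
#' @param probs Named category-to-probability vector (default
#'   [iucn_extinction_probs()]).
#' @return Per-cell risk layer (0 for empty land cells, `NA` off land).
#' @export
extinction_risk <- function(species, grid, probs = iucn_extinction_probs()) {
  unmapped <- setdiff(unique(species$iucn_category), names(probs))
  if (length(unmapped))
    stop("no extinction probability for category: ",
         paste(unmapped, collapse = ", "))
  risk <- rep(0, grid$ncell)
  for (k in seq_len(nrow(species))) {
    cells <- species$cells[[k]]
    if (any(cells < 1 | cells > grid$ncell)) stop("cell id outside grid")
    risk[cells] <- risk[cells] + probs[[species$iucn_category[k]]]
  }
  risk[!grid$land_mask] <- NA_real_
  risk
}

#' Top-decile hotspot cells of a layer
#'
#' Cells at or above the 90th percentile (linear-interpolation quantile) of
#' the layer's valid values; ties at the threshold are kept, so the set is
#' never smaller than a tenth of the valid cells for continuous layers. A
#' constant layer is degenerate: an empty set is returned with a warning.
#'
#' @param values Per-cell layer (`NA` = invalid/masked).
#' @param criterion Label for the map ("richness", "risk" or "debt").
#' @param quantile Threshold quantile (default 0.9 = top 10 percent).
#' @return A `hotspot_set`: list with `criterion`, `threshold`, `members`
#'   (cell ids), `n_valid`, `degenerate`.
#' @export
top_decile_hotspots <- function(values, criterion = "layer", quantile = 0.9) {
  valid <- which(!is.na(values))
  if (length(valid) < 10) stop("need at least 10 valid cells")
  v <- values[valid]
  if (max(v) == min(v)) {
    warning("constant layer: hotspot set is degenerate")
    return(structure(list(criterion = criterion, threshold = NA_real_,
                          members = integer(0), n_valid = length(valid),
                          degenerate = TRUE),
                     class = "hotspot_set"))
  }
  thr <- unname(stats::quantile(v, quantile))
  structure(list(criterion = criterion, threshold = thr,
                 members = valid[v >= thr], n_valid = length(valid),
                 degenerate = FALSE),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("hotspot set (%s): %d of %d cells at threshold %.4g\n",
              x$criterion, length(x$members), x$n_valid, x$threshold))
  invisible(x)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Conservation-gap overlap report
#'
#' Quantifies the spatial mismatch between debt, richness and risk hotspots:
#' pairwise Jaccard indices, the fraction of the debt hotspot covered by the
#' union of the richness and risk hotspots, and the uncovered "gap" cells —
#' high-debt areas not represented in either conventional priority map.
#'
#' @param debt_hs,richness_hs,risk_hs `hotspot_set` objects on one grid.
#' @return An `overlap_report`: list with `jaccard` (named vector),
#'   `coverage`, `gap_fraction`, `gap_cells`.
#' @export
overlap_report <- function(debt_hs, richness_hs, risk_hs) {
  stopifnot(inherits(debt_hs, "hotspot_set"),
            inherits(richness_hs, "hotspot_set"),
            inherits(risk_hs, "hotspot_set"))
  if (length(unique(c(debt_hs$n_valid, richness_hs$n_valid,
                      risk_hs$n_valid))) != 1)
    stop("hotspot sets are not on the same grid")
  d <- debt_hs$members
  covered_set <- union(richness_hs$members, risk_hs$members)
  gap <- setdiff(d, covered_set)
  coverage <- if (length(d)) 1 - length(gap) / length(d) else NA_real_
  structure(list(
    jaccard = c(debt_richness = jaccard(d, richness_hs$members),
                debt_risk = jaccard(d, risk_hs$members),
                richness_risk = jaccard(richness_hs$members, risk_hs$members)),
    coverage = coverage,
    gap_fraction = if (length(d)) length(gap) / length(d) else NA_real_,
    gap_cells = sort(gap)),
    class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("hotspot overlap report\n")
  cat(sprintf("  Jaccard debt~richness %.3f, debt~risk %.3f, richness~risk %.3f\n",
              x$jaccard[1], x$jaccard[2], x$jaccard[3]))
  cat(sprintf("  debt hotspot coverage %.3f (gap fraction %.3f, %d gap cells)\n",
              x$coverage, x$gap_fraction, length(x$gap_cells)))
  invisible(x)
}
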