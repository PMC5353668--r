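# Species records: habitat filtering to terrestrial forest-dwellers and
# rasterization of occupied-cell sets into per-taxon richness maps.

HABITAT_VOCABULARY <- c("forest", "terrestrial", "marine", "freshwater", "other")
IUCN_CATEGORIES <- c("DD", "LC", "NT", "VU", "EN", "CR", "EX", "EW")

#' Construct a species table
#'
#' @param species_id Character ids.
#' @param taxon Taxon group per species (e.g. "reptile", "mammal",
#'   "amphibian").
#' @param habitat List of character vectors of habitat tags per species.
#' @param iucn_category One of `DD, LC, NT, VU, EN, CR, EX, EW` per species.
#' @param cells List of integer vectors of occupied cell ids per species.
#' @return Data frame with list-columns `habitat` and `cells`.
#' @export
species_table <- function(species_id, taxon, habitat, iucn_category, cells) {
  stopifnot(length(species_id) == length(taxon),
            length(taxon) == length(habitat),
            length(habitat) == length(iucn_category),
            length(iucn_category) == length(cells))
  bad <- !iucn_category %in% IUCN_CATEGORIES
  if (any(bad)) stop("unknown IUCN category: ", unique(iucn_category[bad])[1])
  out <- data.frame(species_id = as.character(species_id),
                    taxon = as.character(taxon),
                    iucn_category = as.character(iucn_category),
                    stringsAsFactors = FALSE)
  out$habitat <- I(habitat)
  out$cells <- I(cells)
  out
}

#' Keep terrestrial forest-dwelling species
#'
#' Retains records whose habitat tags include both `"forest"` and
#' `"terrestrial"`; marine, freshwater and other-only species are dropped,
#' matching the habitat screen applied before any richness mapping. Records
#' carrying tags outside the controlled vocabulary are dropped with a
#' warning rather than silently kept.
#'
#' @param species A species table.
#' @return The filtered table, original order preserved.
#' @export
filter_forest_terrestrial <- function(species) {
  if (nrow(species) == 0) return(species)
  known <- vapply(species$habitat,
                  function(h) all(h %in% HABITAT_VOCABULARY), TRUE)
  if (!all(known)) {
    warning(sum(!known), " record(s) with unknown habitat tags dropped")
  }
  keep <- known & vapply(species$habitat,
                         function(h) all(c("forest", "terrestrial") %in% h),
                         TRUE)
  species[keep, , drop = FALSE]
}

#' Rasterize species ranges into a richness map
#'
#' Counts, for each grid cell, the species whose occupied-cell set contains
#' it. Species listed as extinct (`EX`) or extinct in the wild (`EW`) are
#' excluded by default, so the map is extant richness.
#'
#' @param species A species table (typically already habitat-filtered).
#' @param grid A `grid_spec`.
#' @param exclude Categories to exclude (default `c("EX", "EW")`).
#' @return Per-cell integer richness layer (0 on empty land cells, `NA` off
#'   land).
#' @export
rasterize_richness <- function(species, grid, exclude = c("EX", "EW")) {
  counts <- rep(0, grid$ncell)
  use <- !(species$iucn_category %in% exclude)
  cells <- unlist(species$cells[use], use.names = FALSE)
  if (length(cells)) {
    if (any(cells < 1 | cells > grid$ncell)) stop("cell id outside grid")
    if (any(!grid$land_mask[cells])) stop("species occupy non-land cells")
    tab <- tabulate(cells, nbins = grid$ncell)
    counts <- counts + tab
  }
  counts[!grid$land_mask] <- NA_real_
  counts
}

#' Per-taxon richness maps
#'
#' @inheritParams rasterize_richness
#' @return Named list of richness layers, one per taxon present.
#' @export
richness_by_taxon <- function(species, grid, exclude = c("EX", "EW")) {
  taxa <- sort(unique(species$taxon))
  stats::setNames(lapply(taxa, function(tx)
    rasterize_richness(species[species$taxon == tx, , drop = FALSE],
                       grid, exclude)), taxa)
}
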