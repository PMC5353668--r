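# Plain-text interchange: long-format CSV layers and the species table.

#' Write a grid layer as long-format CSV
#'
#' One row per land cell with columns `cell_id`, `lat`, `lon`, `value`.
#'
#' @param grid A `grid_spec`.
#' @param values Layer vector (length `grid$ncell`).
#' @param path Output file path.
#' @export
write_layer_csv <- function(grid, values, path) {
  stopifnot(length(values) == grid$ncell)
  ids <- which(grid$land_mask)
  utils::write.csv(data.frame(cell_id = ids,
                              lat = grid$centroid_lat[ids],
                              lon = grid$centroid_lon[ids],
                              value = values[ids]),
                   path, row.names = FALSE)
}

#' Read a long-format CSV layer onto a grid
#'
#' @param grid A `grid_spec` the file was written against.
#' @param path CSV with columns `cell_id` and `value`.
#' @return A layer vector (`NA` where the file has no row).
#' @export
read_layer_csv <- function(grid, path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("cell_id", "value") %in% names(df)))
  if (any(df$cell_id < 1 | df$cell_id > grid$ncell))
    stop("cell_id outside grid")
  v <- rep(NA_real_, grid$ncell)
  v[df$cell_id] <- df$value
  v
}

#' Write a species table as CSV
#'
#' Occupied cell ids and habitat tags are semicolon-joined into single
#' columns so the table round-trips through plain CSV.
#'
#' @param species Species table (see [generate_species()]).
#' @param path Output file path.
#' @export
write_species_csv <- function(species, path) {
  utils::write.csv(data.frame(
    species_id = species$species_id,
    taxon = species$taxon,
    habitat = vapply(species$habitat, paste, "", collapse = ";"),
    iucn_category = species$iucn_category,
    cell_ids = vapply(species$cells, paste, "", collapse = ";")
  ), path, row.names = FALSE)
}

#' Read a species table written by [write_species_csv()]
#'
#' @param path CSV file path.
#' @return A species table with list-columns `habitat` and `cells`.
#' @export
read_species_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  split_ch <- function(x) strsplit(x, ";", fixed = TRUE)
  out <- data.frame(species_id = df$species_id, taxon = df$taxon,
                    iucn_category = df$iucn_category,
                    stringsAsFactors = FALSE)
  out$habitat <- I(split_ch(df$habitat))
  out$cells <- I(lapply(split_ch(df$cell_ids), as.integer))
  out
}
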