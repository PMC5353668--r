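# Geographic grid geometry: cell construction, spherical areas, great-circle
# distances, von Neumann adjacency. All other modules build on grid_spec.

# IUGG mean Earth radius, km
EARTH_RADIUS_KM <- 6371.0088

#' Build a geographic grid
#'
#' Constructs a regular latitude/longitude grid with cell centroids, spherical
#' cell areas and a land mask. Cells are indexed row-major starting at the
#' northwest corner, so cell 1 is the northernmost, westernmost cell.
#'
#' @param lat_min,lat_max,lon_min,lon_max Grid extent in decimal degrees.
#' @param resolution Cell size in degrees; must divide both extents evenly.
#' @param land_mask Logical vector of length equal to the cell count (row-major
#'   from the northwest), `TRUE` for land. Default: all land.
#' @return An object of class `grid_spec`: a list with the extent, `nlon`,
#'   `nlat`, `ncell`, per-cell `centroid_lat`, `centroid_lon`, `cell_area`
#'   (km^2) and `land_mask`.
#' @examples
#' g <- build_grid(resolution = 10)
#' g$ncell  # 36 x 18 cells
#' @export
build_grid <- function(lat_min = -90, lat_max = 90,
                       lon_min = -180, lon_max = 180,
                       resolution = 1, land_mask = NULL) {
  stopifnot(lat_min < lat_max, lon_min < lon_max,
            lat_min >= -90, lat_max <= 90, resolution > 0)
  nlat <- (lat_max - lat_min) / resolution
  nlon <- (lon_max - lon_min) / resolution
  if (abs(nlat - round(nlat)) > 1e-9 || abs(nlon - round(nlon)) > 1e-9)
    stop("resolution must divide the latitude and longitude extents evenly")
  nlat <- as.integer(round(nlat)); nlon <- as.integer(round(nlon))
  ncell <- nlat * nlon

  row <- rep(seq_len(nlat), each = nlon)    # row 1 = northernmost band
  col <- rep(seq_len(nlon), times = nlat)
  lat_top <- lat_max - (row - 1) * resolution
  centroid_lat <- lat_top - resolution / 2
  centroid_lon <- lon_min + (col - 1) * resolution + resolution / 2
  area <- cell_area(lat_top - resolution, lat_top, resolution)

  if (is.null(land_mask)) land_mask <- rep(TRUE, ncell)
  stopifnot(is.logical(land_mask), length(land_mask) == ncell)
  if (!any(land_mask)) stop("land mask has no land cells")

  structure(list(lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max,
                 resolution = resolution, nlon = nlon, nlat = nlat,
                 ncell = ncell, centroid_lat = centroid_lat,
                 centroid_lon = centroid_lon, cell_area = area,
                 land_mask = land_mask,
                 wraps_lon = isTRUE(all.equal(lon_max - lon_min, 360))),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells at %g deg (%d land)\n",
              x$nlon, x$nlat, x$resolution, sum(x$land_mask)))
  cat(sprintf("  extent lon [%g, %g], lat [%g, %g]\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

#' Spherical area of a latitude/longitude cell
#'
#' Area of the spherical zone slice bounded by two parallels and a longitude
#' width: A = R^2 * dlambda * (sin(lat_top) - sin(lat_bottom)).
#'
#' @param lat_bottom,lat_top Bounding latitudes in degrees, bottom < top.
#' @param lon_width Longitudinal width in degrees.
#' @return Area in km^2 (vectorised over the latitude bounds).
#' @export
cell_area <- function(lat_bottom, lat_top, lon_width) {
  if (any(lat_bottom >= lat_top)) stop("lat_bottom must be < lat_top")
  if (any(lat_bottom < -90) || any(lat_top > 90))
    stop("latitudes must lie in [-90, 90]")
  EARTH_RADIUS_KM^2 * (lon_width * pi / 180) *
    (sin(lat_top * pi / 180) - sin(lat_bottom * pi / 180))
}

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0088 km; vectorised.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in km.
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Pairwise great-circle distances between land-cell centroids
#'
#' @param grid A `grid_spec`.
#' @param cutoff Optional radius in km; entries beyond it are set to `NA`
#'   (treated as zero contribution by the metric kernels).
#' @return A symmetric matrix with zero diagonal whose rows/columns correspond
#'   to land cells; their cell ids are in `attr(, "cell_ids")`.
#' @export
distance_matrix <- function(grid, cutoff = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.null(cutoff) && cutoff < 0) stop("cutoff must be non-negative")
  ids <- which(grid$land_mask)
  lat <- grid$centroid_lat[ids]; lon <- grid$centroid_lon[ids]
  n <- length(ids)
  d <- matrix(0, n, n)
  # haversine row blocks against all columns
  for (i in seq_len(n)) {
    d[i, ] <- great_circle_distance(lat[i], lon[i], lat, lon)
  }
  d <- (d + t(d)) / 2          # enforce exact symmetry
  diag(d) <- 0
  if (!is.null(cutoff)) {
    beyond <- d > cutoff
    diag(beyond) <- FALSE
    d[beyond] <- NA_real_
  }
  attr(d, "cell_ids") <- ids
  d
}

#' Von Neumann neighbors of a cell
#'
#' The four orthogonally adjacent cells. Longitude wraps when the grid spans
#' 360 degrees (the dateline is adjacent); latitude clamps, so cells in the
#' polar rows have three neighbors. Neighbors are geometric: masked (ocean)
#' cells are still returned and it is up to the metric to ignore them.
#'
#' @param grid A `grid_spec`.
#' @param cell Integer cell id.
#' @return Integer vector of neighbor cell ids.
#' @export
cell_neighbors <- function(grid, cell) {
  stopifnot(cell >= 1, cell <= grid$ncell)
  nlon <- grid$nlon
  row <- (cell - 1L) %/% nlon + 1L
  col <- (cell - 1L) %% nlon + 1L
  out <- integer(0)
  if (row > 1L) out <- c(out, cell - nlon)
  if (row < grid$nlat) out <- c(out, cell + nlon)
  left <- col - 1L; right <- col + 1L
  if (grid$wraps_lon) {
    if (left < 1L) left <- nlon
    if (right > nlon) right <- 1L
    out <- c(out, (row - 1L) * nlon + left, (row - 1L) * nlon + right)
  } else {
    if (left >= 1L) out <- c(out, (row - 1L) * nlon + left)
    if (right <= nlon) out <- c(out, (row - 1L) * nlon + right)
  }
  sort(unique(out))
}

#' Create a grid layer
#'
#' A layer is a plain numeric vector of length `grid$ncell` with `NA` on
#' masked (non-land) cells; arithmetic on layers propagates missingness.
#'
#' @param grid A `grid_spec`.
#' @param values A scalar or vector of per-cell values.
#' @return Numeric vector of length `grid$ncell`, `NA` off land.
#' @export
grid_layer <- function(grid, values = NA_real_) {
  stopifnot(inherits(grid, "grid_spec"))
  v <- rep_len(as.numeric(values), grid$ncell)
  if (length(values) > 1 && length(values) != grid$ncell)
    stop("values must be scalar or of length grid$ncell")
  v[!grid$land_mask] <- NA_real_
  v
}
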