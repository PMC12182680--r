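#' Grid geometry for gridded worlds
#'
#' A lightweight description of a regular latitude/longitude lattice. Rasters
#' in this package are plain numeric/integer matrices stored north-up (row 1
#' is the northernmost row); a `grid_geom` carries the georeferencing needed
#' to compute latitude-dependent cell areas and to write files.
#'
#' @param nrow,ncol Grid dimensions (rows = latitude bands, columns =
#'   longitude bands). Must be >= 2.
#' @param cell_size Cell edge length in degrees (same in both axes).
#' @param lat_origin Latitude of the NORTHERN edge of row 1, degrees.
#' @param lon_origin Longitude of the western edge of column 1, degrees.
#' @return An object of class `grid_geom`.
#' @examples
#' g <- grid_geom(10, 10, cell_size = 0.5, lat_origin = 53)
#' range(cell_area_ha(g))
#' @export
grid_geom <- function(nrow, ncol, cell_size = 0.5, lat_origin = 53,
                      lon_origin = 75) {
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  if (is.na(nrow) || is.na(ncol) || nrow < 2L || ncol < 2L)
    stop("configuration error: grid dimensions must be integers >= 2")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("configuration error: cell_size must be positive")
  if (lat_origin > 90 || lat_origin - nrow * cell_size < -90)
    stop("configuration error: grid extends beyond valid latitudes")
  structure(list(nrow = nrow, ncol = ncol, cell_size = cell_size,
                 lat_origin = lat_origin, lon_origin = lon_origin),
            class = "grid_geom")
}

#' @export
print.grid_geom <- function(x, ...) {
  cat(sprintf("grid_geom: %d x %d cells of %g deg, N edge %g, W edge %g\n",
              x$nrow, x$ncol, x$cell_size, x$lat_origin, x$lon_origin))
  invisible(x)
}

#' Latitude of row centres
#' @param geom A [grid_geom()].
#' @return Numeric vector of length `geom$nrow` (degrees).
#' @export
lat_centers <- function(geom) {
  geom$lat_origin - (seq_len(geom$nrow) - 0.5) * geom$cell_size
}

# mean Earth radius, metres (IUGG)
.R_EARTH <- 6371008.8

#' Spherical cell areas by row
#'
#' Area of one cell in each latitude band, in hectares, using the spherical
#' formula R^2 * dlon * (sin(lat_top) - sin(lat_bottom)), so area accounting
#' (Mha totals) is latitude-correct.
#'
#' @param geom A [grid_geom()].
#' @return Numeric vector of length `geom$nrow`: hectares per cell in each row.
#' @export
cell_area_ha <- function(geom) {
  top <- geom$lat_origin - (seq_len(geom$nrow) - 1) * geom$cell_size
  bot <- top - geom$cell_size
  dlon <- geom$cell_size * pi / 180
  m2 <- .R_EARTH^2 * dlon * (sin(top * pi / 180) - sin(bot * pi / 180))
  m2 / 1e4
}

#' Matrix of per-cell areas
#' @param geom A [grid_geom()].
#' @return Matrix (`geom$nrow` x `geom$ncol`) of cell areas in hectares.
#' @export
cell_area_matrix <- function(geom) {
  matrix(cell_area_ha(geom), nrow = geom$nrow, ncol = geom$ncol)
}

#' Write a raster matrix as an ESRI ASCII grid
#'
#' Plain-text single-band raster output. Continuous values are written as-is;
#' pass an integer matrix for categorical layers. `NA` cells are written as
#' the declared nodata value.
#'
#' @param m Matrix, rows north-up.
#' @param path Output file path.
#' @param geom A [grid_geom()] describing `m`.
#' @param nodata Value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, geom, nodata = -9999) {
  stopifnot(is.matrix(m), nrow(m) == geom$nrow, ncol(m) == geom$ncol)
  hdr <- c(
    sprintf("ncols %d", geom$ncol),
    sprintf("nrows %d", geom$nrow),
    sprintf("xllcorner %.10g", geom$lon_origin),
    sprintf("yllcorner %.10g", geom$lat_origin - geom$nrow * geom$cell_size),
    sprintf("cellsize %.10g", geom$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  mm <- m
  mm[is.na(mm)] <- nodata
  rows <- apply(mm, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                          collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any ESRI ASCII grid).
#' @return A list with elements `values` (matrix, `NA` where nodata) and
#'   `geom` (a [grid_geom()]).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- as.numeric(kv[, 2])
  names(vals) <- tolower(kv[, 1])
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  body <- lines[-(1:6)]
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
              nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA
  geom <- grid_geom(nr, nc, cell_size = vals[["cellsize"]],
                    lat_origin = vals[["yllcorner"]] + nr * vals[["cellsize"]],
                    lon_origin = vals[["xllcorner"]])
  list(values = m, geom = geom)
}

#' Nearest-neighbour regridding
#'
#' Convenience utility for bringing a product onto a different lattice of the
#' same extent. Nearest-neighbour is used so categorical codes are preserved.
#' The core fusion operations require inputs that already share a grid.
#'
#' @param m Input matrix.
#' @param nrow_out,ncol_out Output dimensions.
#' @return Matrix of dimension `nrow_out` x `ncol_out`.
#' @export
regrid_nearest <- function(m, nrow_out, ncol_out) {
  ri <- pmin(nrow(m), pmax(1L, ceiling((seq_len(nrow_out) - 0.5) *
                                         nrow(m) / nrow_out)))
  ci <- pmin(ncol(m), pmax(1L, ceiling((seq_len(ncol_out) - 0.5) *
                                         ncol(m) / ncol_out)))
  m[ri, ci, drop = FALSE]
}
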