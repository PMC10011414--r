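#' Define a regular analysis grid
#'
#' All rasters in the package are plain numeric/logical matrices laid out on a
#' shared `grid_spec`: row 1 is the top row, column 1 the left column, and cell
#' `(r, c)` covers the square
#' `[x0 + (c-1)s, x0 + c*s) x (y0 - r*s, y0 - (r-1)*s]` in km, where `s` is
#' the cell size and `(x0, y0)` the top-left origin. The default origin
#' `(0, n_rows * s)` makes the grid span `[0, W) x (0, H]`.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size_km Cell edge length in km (default 1, the analysis grain).
#' @param origin Numeric length-2, `(x0, y0)` of the top-left corner in km.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_km = 1,
                      origin = c(0, n_rows * cell_size_km)) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != as.integer(n_rows) || n_cols != as.integer(n_cols)) {
    stop("n_rows and n_cols must be positive integers")
  }
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1L ||
      !is.finite(cell_size_km) || cell_size_km <= 0) {
    stop("cell_size_km must be a positive number")
  }
  if (length(origin) != 2L || !all(is.finite(origin))) {
    stop("origin must be two finite numbers (x0, y0)")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size_km = as.numeric(cell_size_km),
         origin = as.numeric(origin)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, %.3g km cells, origin (%.3g, %.3g)\n",
              x$n_rows, x$n_cols, x$cell_size_km, x$origin[1], x$origin[2]))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell-centre coordinates
#'
#' @param grid A [grid_spec()].
#' @param rows,cols Integer vectors of row/column indices (1-based).
#' @return A two-column matrix of `(x_km, y_km)` cell centres.
#' @export
cell_centres <- function(grid, rows, cols) {
  s <- grid$cell_size_km
  cbind(x_km = grid$origin[1] + (cols - 0.5) * s,
        y_km = grid$origin[2] - (rows - 0.5) * s)
}

#' Map points to grid cells
#'
#' @param grid A [grid_spec()].
#' @param x,y Point coordinates in km.
#' @return A data.frame with columns `row`, `col` (NA for points outside the
#'   grid extent).
#' @export
cells_from_xy <- function(grid, x, y) {
  s <- grid$cell_size_km
  col <- floor((x - grid$origin[1]) / s) + 1L
  # y half-open on [y0 - r*s, y0 - (r-1)*s): top edge belongs to the row below
  row <- floor((grid$origin[2] - y) / s) + 1L
  bad <- !is.finite(row) | !is.finite(col) |
    row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

cell_index <- function(grid, row, col) (col - 1L) * grid$n_rows + row

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("grids do not match")
  invisible(TRUE)
}

#' Write a raster matrix as an ESRI ASCII grid
#'
#' Rasters are serialized in the plain-text ESRI ASCII grid format (`.asc`):
#' a six-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) followed by rows of whitespace-separated values, top row
#' first. NA cells are written as the nodata value.
#'
#' @param mat Numeric or logical matrix (rows = grid rows, top first).
#' @param grid The [grid_spec()] the matrix lies on.
#' @param path Output file path.
#' @param nodata Value standing in for NA (default -9999).
#' @export
write_ascii_raster <- function(mat, grid, path, nodata = -9999) {
  stopifnot(nrow(mat) == grid$n_rows, ncol(mat) == grid$n_cols)
  m <- mat
  storage.mode(m) <- "double"
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  s <- grid$cell_size_km
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2] - grid$n_rows * s),
    sprintf("cellsize %.10g", s),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_raster()] (or any conforming
#'   `.asc` file).
#' @return A list with elements `mat` (numeric matrix, nodata as NA) and
#'   `grid` (a [grid_spec()]).
#' @export
read_ascii_raster <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  vals <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                          tolower(vapply(kv, `[`, "", 1)))
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  m <- matrix(scan(path, skip = 6, quiet = TRUE), nrow = nr, ncol = nc,
              byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA
  g <- grid_spec(nr, nc, vals[["cellsize"]],
                 origin = c(vals[["xllcorner"]],
                            vals[["yllcorner"]] + nr * vals[["cellsize"]]))
  list(mat = m, grid = g)
}
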